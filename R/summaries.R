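# Reporting-layer arithmetic over benchmark compositions and calibration
# summaries. These helpers operate on plain count tables so that published
# or externally produced summaries can be checked with the same code paths
# used for the package's own reports.

#' Totals of a benchmark composition table
#'
#' Sums per-dataset benign and pathogenic variant counts into combined
#' totals.
#'
#' @param composition A data.frame with columns \code{Benign} and
#'   \code{Pathogenic}, one row per dataset.
#' @return A list with \code{benign}, \code{pathogenic} and \code{total}.
#' @export
combinedTotals <- function(composition) {
    stopifnot(all(c("Benign", "Pathogenic") %in% colnames(composition)))
    b <- sum(composition$Benign)
    p <- sum(composition$Pathogenic)
    list(benign = b, pathogenic = p, total = b + p)
}

#' Benign-set accounting balance
#'
#' The conservation identity of [matchBenignSet()]: the equalized benign
#' set size implied by a candidate count and the per-stage removal counts.
#'
#' @param accounting Named numeric vector with \code{nCandidates},
#'   \code{removedKnown}, \code{removedAf}, \code{removedStepOver} (as in
#'   the [matchBenignSet()] result).
#' @return The implied equalized set size.
#' @export
accountingBalance <- function(accounting) {
    unname(accounting[["nCandidates"]] - accounting[["removedKnown"]] -
           accounting[["removedAf"]] - accounting[["removedStepOver"]])
}

#' Mean CADD separation
#'
#' Gene-averaged CADD gap: the difference between the mean of per-gene
#' pathogenic mean CADD scores and the mean of per-gene benign mean CADD
#' scores.
#'
#' @param x A \linkS4class{GeneCalibrations} object, or a list/data.frame
#'   with \code{MeanPathogenicCadd} and \code{MeanPopulationCadd}.
#' @return A list with \code{pathogenic}, \code{benign} (the two means of
#'   means) and \code{gap}.
#' @export
caddSeparation <- function(x) {
    p <- x$MeanPathogenicCadd
    b <- x$MeanPopulationCadd
    keep <- !is.na(p) & !is.na(b)
    mp <- mean(p[keep])
    mb <- mean(b[keep])
    list(pathogenic = mp, benign = mb, gap = mp - mb)
}
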