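# Construction and accessors for the gene calibration table.

#' Build a GeneCalibrations object from a data.frame
#'
#' Internal-facing constructor; users normally obtain calibrations from
#' [calibrateGenes()] or [readCalibrationTable()].
#'
#' @param df A data.frame (or DataFrame) with the calibration columns.
#' @return A \linkS4class{GeneCalibrations} object.
#' @export
GeneCalibrations <- function(df) {
    df <- as(as.data.frame(df, stringsAsFactors = FALSE), "DataFrame")
    for (col in setdiff(CALIBRATION_COLUMNS, colnames(df))) {
        df[[col]] <- rep(if (col %in% c("NPathogenic", "NBenign"))
                             NA_integer_ else NA_character_, nrow(df))
    }
    df <- df[, CALIBRATION_COLUMNS]
    num <- c("PathoMafThreshold", "MeanPathogenicCadd", "MeanPopulationCadd",
             "Sens95CaddThreshold", "Spec95CaddThreshold", "MwuPValue")
    for (col in num) df[[col]] <- as.numeric(df[[col]])
    df$NPathogenic <- as.integer(df$NPathogenic)
    df$NBenign <- as.integer(df$NBenign)
    df$Gene <- as.character(df$Gene)
    df$Category <- as.character(df$Category)
    df$PathogenicImpactDistribution <-
        as.character(df$PathogenicImpactDistribution)
    df$BenignImpactDistribution <- as.character(df$BenignImpactDistribution)
    rownames(df) <- df$Gene
    new("GeneCalibrations", df)
}

#' @rdname GeneCalibrations-class
#' @param x A \linkS4class{GeneCalibrations} object.
#' @export
setGeneric("calibratedGenes", function(x) standardGeneric("calibratedGenes"))
#' @rdname GeneCalibrations-class
setMethod("calibratedGenes", "GeneCalibrations", function(x) x$Gene)

#' @rdname GeneCalibrations-class
#' @param gene A single gene symbol.
#' @export
setGeneric("calibrationFor", function(x, gene)
    standardGeneric("calibrationFor"))

#' @rdname GeneCalibrations-class
#' @return \code{calibrationFor} returns a one-element list per field for the
#'   requested gene (with impact distributions decoded to named numeric
#'   vectors), or \code{NULL} when the gene has no calibration row.
setMethod("calibrationFor", "GeneCalibrations", function(x, gene) {
    i <- match(gene, x$Gene)
    if (is.na(i)) return(NULL)
    row <- as.data.frame(x[i, , drop = FALSE], stringsAsFactors = FALSE)
    out <- as.list(row)
    out$PathogenicImpactDistribution <-
        .stringToDist(row$PathogenicImpactDistribution)
    out$BenignImpactDistribution <-
        .stringToDist(row$BenignImpactDistribution)
    out
})

#' Tabulate calibration outcome categories
#'
#' Counts genes per calibration category and their total; the categories
#' partition the calibrated gene set, so the total always equals the number
#' of rows.
#'
#' @param x A \linkS4class{GeneCalibrations} object, or a named numeric
#'   vector of per-category gene counts.
#' @return A list with \code{counts} (named integer vector over all seven
#'   categories) and \code{total}.
#' @export
categoryCounts <- function(x) {
    if (is(x, "GeneCalibrations")) {
        counts <- table(factor(x$Category, levels = CALIBRATION_CATEGORIES))
        counts <- structure(as.integer(counts), names = names(counts))
    } else {
        counts <- structure(as.integer(x), names = names(x))
    }
    list(counts = counts, total = sum(counts))
}

setMethod("show", "GeneCalibrations", function(object) {
    cat("GeneCalibrations with", nrow(object), "gene(s)\n")
    cc <- categoryCounts(object)$counts
    cc <- cc[cc > 0]
    if (length(cc) > 0L) {
        cat("  ", paste(names(cc), cc, sep = "=", collapse = " "), "\n")
    }
    invisible(callNextMethod())
})
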