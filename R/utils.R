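# Shared vocabularies and small internal helpers.

#' Effect impact categories, most to least severe
#'
#' SnpEff-style generalized effect impact levels, ordered by decreasing
#' severity. Used throughout for impact distributions and the impact-direct
#' classification rule.
#' @export
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Gene calibration outcome categories
#'
#' The seven mutually exclusive outcomes of per-gene calibration:
#' \describe{
#'   \item{CADD_PREDICTIVE}{CADD separates pathogenic from matched benign
#'     variants (Mann-Whitney p < alpha, pathogenic mean higher).}
#'   \item{CADD_LESS_PREDICTIVE}{Enough data, but no significant separation.}
#'   \item{LITTLE_DATA}{Fewer than \code{minN} variants in either group.}
#'   \item{IMPACT_PREDICTIVE}{Some impact category occurs only in pathogenic
#'     variants; impact is used as a direct classifier.}
#'   \item{MAF_ONLY}{Only the pathogenic allele-frequency ceiling could be
#'     calibrated (no usable benign set or no CADD coverage).}
#'   \item{NOT_CALIBRATED}{Fewer than 2 usable variants in the gene.}
#'   \item{ARTIFACT}{Significant separation in the wrong direction
#'     (population CADD above pathogenic CADD).}
#' }
#' @export
CALIBRATION_CATEGORIES <- c(
    "CADD_PREDICTIVE", "CADD_LESS_PREDICTIVE", "LITTLE_DATA",
    "IMPACT_PREDICTIVE", "MAF_ONLY", "NOT_CALIBRATED", "ARTIFACT"
)

TRUTH_LABELS <- c("BENIGN", "PATHOGENIC", "VUS")

# numeric severity rank: HIGH = 4 ... MODIFIER = 1
.impactRank <- function(impact) {
    length(IMPACT_LEVELS) + 1L - match(impact, IMPACT_LEVELS)
}

# serialize / parse an impact distribution for the calibration table
.distToString <- function(d) {
    if (all(is.na(d))) return(NA_character_)
    paste(formatC(unname(d[IMPACT_LEVELS]), format = "g", digits = 8),
          collapse = ",")
}

.stringToDist <- function(s) {
    if (is.na(s) || !nzchar(s)) {
        return(structure(rep(NA_real_, 4L), names = IMPACT_LEVELS))
    }
    v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
    if (length(v) != 4L) {
        stop("malformed impact distribution string: ", s)
    }
    structure(v, names = IMPACT_LEVELS)
}

# evaluate expr with a temporary RNG state seeded from `seed`,
# restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# x %||% y for scalar NA handling
.orElse <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x
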