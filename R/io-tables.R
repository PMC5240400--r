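# Tabular artifacts: the calibration table and the gene-to-panel map.

#' Read a gene calibration table
#'
#' Parses the TSV written by [writeCalibrationTable()]: one row per gene
#' with the calibration category, thresholds, impact distributions, group
#' sizes and Mann-Whitney p value. Threshold fields are empty exactly where
#' the category implies they were not computed.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{GeneCalibrations} object.
#' @export
readCalibrationTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    required <- setdiff(CALIBRATION_COLUMNS, "BenignImpactDistribution")
    missing <- setdiff(required, colnames(df))
    if (length(missing) > 0L) {
        stop("calibration table is missing column(s): ",
             paste(missing, collapse = ", "))
    }
    if (anyDuplicated(df$Gene)) {
        stop("calibration table has duplicate gene symbol(s): ",
             paste(unique(df$Gene[duplicated(df$Gene)]), collapse = ", "))
    }
    bad <- !(df$Category %in% CALIBRATION_CATEGORIES)
    if (any(bad)) {
        stop("calibration table has unknown category token(s): ",
             paste(unique(df$Category[bad]), collapse = ", "))
    }
    GeneCalibrations(df)
}

#' Write a gene calibration table
#'
#' @param calibrations A \linkS4class{GeneCalibrations} object.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCalibrationTable <- function(calibrations, path) {
    stopifnot(is(calibrations, "GeneCalibrations"))
    df <- as.data.frame(calibrations, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a gene-to-manifestation-category map
#'
#' Parses a Clinical Genomics Database style TSV mapping gene symbols to
#' organ-system manifestation categories. A gene listed on several rows
#' accumulates the union of its categories.
#'
#' @param path Path to the TSV file.
#' @param geneColumn Name of the gene column (default \code{Gene}).
#' @param categoryColumn Name of the category-list column; by default the
#'   first column whose name contains "manifestation" (case-insensitive).
#' @param delim Regular expression splitting the category list (default
#'   semicolon or comma).
#' @return A named list: gene symbol to character vector of categories
#'   (whitespace-trimmed, non-empty).
#' @export
readCgd <- function(path, geneColumn = "Gene", categoryColumn = NULL,
                    delim = "[;,]") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (is.null(categoryColumn)) {
        hit <- grep("manifestation", colnames(df), ignore.case = TRUE)
        if (length(hit) == 0L) {
            stop("no manifestation-categories column found in ", path)
        }
        categoryColumn <- colnames(df)[hit[1L]]
    }
    if (!geneColumn %in% colnames(df)) {
        stop("missing required column '", geneColumn, "' in ", path)
    }
    if (!categoryColumn %in% colnames(df)) {
        stop("missing required column '", categoryColumn, "' in ", path)
    }
    out <- list()
    for (i in seq_len(nrow(df))) {
        cats <- trimws(strsplit(as.character(df[[categoryColumn]][i]),
                                delim)[[1L]])
        cats <- cats[nzchar(cats)]
        g <- as.character(df[[geneColumn]][i])
        out[[g]] <- sort(unique(c(out[[g]], cats)))
    }
    out
}
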