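# Three-outcome benchmark metrics, panel stratification and the bootstrap
# comparison of gene-specific against genome-wide thresholds.

#' Score verdicts against binary truth labels
#'
#' Three-outcome confusion accounting: a VUS verdict on a truth-pathogenic
#' (truth-benign) variant counts as a missed positive (missed negative),
#' not as an error. Metrics use the missed-inclusive denominators:
#' \deqn{sensitivity = TP / (TP + FN + missedPos)}
#' \deqn{specificity = TN / (TN + FP + missedNeg)}
#' \deqn{accuracy = (TP + TN) / (TP + TN + FP + FN + missedPos + missedNeg)}
#'
#' @param truth Character vector of truth labels, \code{BENIGN} or
#'   \code{PATHOGENIC} only.
#' @param verdict Character vector of classifier verdicts, \code{Benign},
#'   \code{Pathogenic} or \code{VUS} (case-insensitive).
#' @return A list with \code{counts} (named integer vector \code{tp},
#'   \code{tn}, \code{fp}, \code{fn}, \code{missedPos}, \code{missedNeg})
#'   and \code{sensitivity}, \code{specificity}, \code{accuracy}
#'   (\code{NA} on an empty denominator).
#' @export
scoreJudgments <- function(truth, verdict) {
    truth <- toupper(as.character(truth))
    verdict <- toupper(as.character(verdict))
    if (any(!truth %in% c("BENIGN", "PATHOGENIC"))) {
        stop("scoreJudgments: truth labels must be BENIGN or PATHOGENIC")
    }
    if (any(!verdict %in% c("BENIGN", "PATHOGENIC", "VUS"))) {
        stop("scoreJudgments: verdicts must be Benign, Pathogenic or VUS")
    }
    if (length(truth) != length(verdict)) {
        stop("scoreJudgments: truth and verdict lengths differ")
    }
    isP <- truth == "PATHOGENIC"
    counts <- c(
        tp = sum(isP & verdict == "PATHOGENIC"),
        tn = sum(!isP & verdict == "BENIGN"),
        fp = sum(!isP & verdict == "PATHOGENIC"),
        fn = sum(isP & verdict == "BENIGN"),
        missedPos = sum(isP & verdict == "VUS"),
        missedNeg = sum(!isP & verdict == "VUS")
    )
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    list(
        counts = counts,
        sensitivity = ratio(counts[["tp"]],
                            counts[["tp"]] + counts[["fn"]] +
                            counts[["missedPos"]]),
        specificity = ratio(counts[["tn"]],
                            counts[["tn"]] + counts[["fp"]] +
                            counts[["missedNeg"]]),
        accuracy = ratio(counts[["tp"]] + counts[["tn"]], sum(counts))
    )
}

#' Predictive values over classified variants only
#'
#' Positive and negative predictive value with missed (VUS / unclassified)
#' variants excluded from the denominators, the appropriate lens for
#' abstaining predictors.
#'
#' @param counts Named counts as returned in
#'   \code{scoreJudgments(...)$counts}.
#' @return A list with \code{ppv} = tp / (tp + fp) and \code{npv} =
#'   tn / (tn + fn), \code{NA} on an empty denominator.
#' @export
predictiveValues <- function(counts) {
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    list(ppv = ratio(counts[["tp"]], counts[["tp"]] + counts[["fp"]]),
         npv = ratio(counts[["tn"]], counts[["tn"]] + counts[["fn"]]))
}

#' Stratify variants into manifestation panels
#'
#' Assigns every variant to the panel of each manifestation category linked
#' to any of its genes. A variant appears at most once per panel even when
#' several of its genes share a category, and falls into the special
#' \code{NotInCGD} panel only when none of its genes occur in the map.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object (one instance
#'   per gene; instances sharing chrom/pos/ref/alt are one variant).
#' @param cgd Named list from [readCgd()].
#' @return A named list of integer index vectors into \code{variants}, one
#'   per panel (first instance per distinct variant), including
#'   \code{NotInCGD}.
#' @export
stratifyByPanel <- function(variants, cgd) {
    stopifnot(is(variants, "AnnotatedVariants"))
    key <- variantKey(variants)
    gene <- geneSymbol(variants)
    panels <- list()
    inCgd <- logical(length(variants))
    for (i in seq_along(variants)) {
        g <- gene[i]
        if (!is.na(g) && !is.null(cgd[[g]])) {
            inCgd[i] <- TRUE
            for (cat in cgd[[g]]) panels[[cat]] <- c(panels[[cat]], i)
        }
    }
    cgdKeys <- unique(key[inCgd])
    panels[["NotInCGD"]] <- which(!key %in% cgdKeys)
    lapply(panels, function(idx) idx[!duplicated(key[idx])])
}

#' Benchmark report over panels
#'
#' Scores a classified, truth-labelled variant set per manifestation panel
#' (plus a combined row), in the layout of a per-dataset benchmark table.
#'
#' @param variants Truth-labelled \linkS4class{AnnotatedVariants}.
#' @param verdicts Character verdicts parallel to \code{variants}.
#' @param cgd Optional named list from [readCgd()]; when \code{NULL} only
#'   the combined row is produced.
#' @return A data.frame with one row per panel: \code{panel}, \code{n},
#'   \code{nPathogenic}, the six confusion counts, \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, \code{ppv}, \code{npv}.
#' @export
benchmarkReport <- function(variants, verdicts, cgd = NULL) {
    stopifnot(is(variants, "AnnotatedVariants"))
    truth <- truthLabel(variants)
    usable <- !is.na(truth) & truth %in% c("BENIGN", "PATHOGENIC")
    sets <- list(Combined = which(usable))
    if (!is.null(cgd)) {
        strata <- stratifyByPanel(variants, cgd)
        for (p in names(strata)) {
            sets[[p]] <- strata[[p]][usable[strata[[p]]]]
        }
    }
    rows <- lapply(names(sets), function(p) {
        idx <- sets[[p]]
        if (length(idx) == 0L) {
            return(NULL)
        }
        sc <- scoreJudgments(truth[idx], verdicts[idx])
        pv <- predictiveValues(sc$counts)
        data.frame(panel = p, n = length(idx),
                   nPathogenic = sum(truth[idx] == "PATHOGENIC"),
                   t(sc$counts),
                   sensitivity = sc$sensitivity,
                   specificity = sc$specificity, accuracy = sc$accuracy,
                   ppv = pv$ppv, npv = pv$npv, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Bootstrap comparison of two classifiers
#'
#' Draws \code{nSamples} bootstrap replicates, each sampling (with
#' replacement) \code{nBenign} truth-benign and \code{nPatho}
#' truth-pathogenic variants from the set, and computes the
#' missed-inclusive accuracy of both classifiers on identical samples. Used
#' to compare gene-specific thresholds against the genome-wide fallback on
#' groups of genes.
#'
#' @param variants Truth-labelled \linkS4class{AnnotatedVariants}.
#' @param classifierA,classifierB Functions mapping an
#'   \linkS4class{AnnotatedVariants} object to a character vector of
#'   verdicts, e.g. from [geneSpecificClassifier()] or
#'   [genomeWideClassifier()]; each is evaluated once on the full set.
#' @param nSamples Number of bootstrap replicates (default 10000).
#' @param nBenign,nPatho Per-replicate sample sizes (default 100 each).
#' @param seed Integer seed; replicates are reproducible under it.
#' @return A list with \code{accuracyA}, \code{accuracyB} (numeric vectors
#'   of length \code{nSamples}), \code{medianA}, \code{medianB} and
#'   \code{mwuP}, the two-sided Mann-Whitney p value comparing the two
#'   accuracy distributions.
#' @export
bootstrapCompare <- function(variants, classifierA, classifierB,
                             nSamples = 10000L, nBenign = 100L,
                             nPatho = 100L, seed = 1L) {
    stopifnot(is(variants, "AnnotatedVariants"))
    truth <- toupper(truthLabel(variants))
    bIdx <- which(truth == "BENIGN")
    pIdx <- which(truth == "PATHOGENIC")
    if (length(bIdx) < nBenign) {
        stop("bootstrapCompare: insufficient truth-benign variants (",
             length(bIdx), " < ", nBenign, ")")
    }
    if (length(pIdx) < nPatho) {
        stop("bootstrapCompare: insufficient truth-pathogenic variants (",
             length(pIdx), " < ", nPatho, ")")
    }
    vA <- toupper(classifierA(variants))
    vB <- toupper(classifierB(variants))
    accOf <- function(v, idx) {
        correct <- sum((truth[idx] == "PATHOGENIC" &
                        v[idx] == "PATHOGENIC") |
                       (truth[idx] == "BENIGN" & v[idx] == "BENIGN"))
        correct / length(idx)
    }
    res <- .withSeed(seed, {
        accA <- numeric(nSamples)
        accB <- numeric(nSamples)
        for (r in seq_len(nSamples)) {
            idx <- c(sample(bIdx, nBenign, replace = TRUE),
                     sample(pIdx, nPatho, replace = TRUE))
            accA[r] <- accOf(vA, idx)
            accB[r] <- accOf(vB, idx)
        }
        list(accA = accA, accB = accB)
    })
    p <- if (identical(res$accA, res$accB)) 1
         else mannWhitneyU(res$accA, res$accB)$p
    list(accuracyA = res$accA, accuracyB = res$accB,
         medianA = stats::median(res$accA), medianB = stats::median(res$accB),
         mwuP = p)
}

#' Classifier closures for bootstrap comparisons
#'
#' \code{geneSpecificClassifier} classifies with gene calibrations (and the
#' genome-wide fallback behind them); \code{genomeWideClassifier} uses the
#' fixed genome-wide thresholds only.
#'
#' @param calibrations A \linkS4class{GeneCalibrations} object.
#' @param defaults Genome-wide thresholds (see [genomeWideDefaults()]).
#' @param setting Sensitivity-adjustment setting (default 5).
#' @param ... Forwarded to [classifyVariants()].
#' @return A function mapping \linkS4class{AnnotatedVariants} to a
#'   character vector of verdicts.
#' @export
geneSpecificClassifier <- function(calibrations, defaults, setting = 5,
                                   ...) {
    force(calibrations); force(defaults); force(setting)
    function(variants) {
        classifyVariants(variants, calibrations, defaults,
                         setting = setting, ...)$verdict
    }
}

#' @rdname geneSpecificClassifier
#' @export
genomeWideClassifier <- function(defaults) {
    force(defaults)
    function(variants) {
        classifyVariants(variants, NULL, defaults)$verdict
    }
}
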