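# Per-gene calibration: pathogenic MAF ceiling, matched benign set,
# CADD statistics and the seven-way category assignment.

#' Select pathogenic variants by clinical significance
#'
#' Keeps variants whose clinical-significance string contains the word
#' "pathogenic" case-insensitively, so that "Likely pathogenic" is included,
#' mirroring how calibration training sets are drawn from clinical variant
#' archives. An optional negation list drops significance strings matching
#' any of its patterns (default: none, i.e. the plain substring rule).
#' Variants without a significance string fall back to their enumerated
#' truth label.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object.
#' @param negations Character vector of case-insensitive substrings whose
#'   presence excludes a variant despite matching "pathogenic".
#' @return The pathogenic subset of \code{variants} (possibly empty).
#' @export
selectPathogenic <- function(variants, negations = character(0)) {
    stopifnot(is(variants, "AnnotatedVariants"))
    sig <- mcols(variants)$significance
    lab <- mcols(variants)$label
    keep <- ifelse(!is.na(sig),
                   grepl("pathogenic", sig, ignore.case = TRUE),
                   !is.na(lab) & lab == "PATHOGENIC")
    for (neg in negations) {
        keep <- keep & !(!is.na(sig) & grepl(neg, sig, ignore.case = TRUE))
    }
    variants[keep]
}

#' Pathogenic allele-frequency ceiling
#'
#' The gene-specific pathogenic MAF threshold: the type-7 95th percentile of
#' the population allele frequencies of the gene's pathogenic variants, with
#' variants absent from the population assigned frequency zero. Benign
#' candidates above this ceiling are considered too common to fall into the
#' pathogenic frequency range.
#'
#' @param patho Pathogenic \linkS4class{AnnotatedVariants} for one gene.
#' @param p Percentile level (default 0.95).
#' @return A single numeric threshold, or \code{NA} for an empty set.
#' @export
pathoMafThreshold <- function(patho, p = 0.95) {
    if (length(patho) == 0L) return(NA_real_)
    af <- alleleFreq(patho)
    af[is.na(af)] <- 0
    percentileR7(af, p)
}

#' Impact category distribution
#'
#' Relative proportion of the four generalized effect impact categories in a
#' variant set.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object; every variant
#'   must carry an impact annotation.
#' @return Named numeric vector over \code{HIGH}, \code{MODERATE},
#'   \code{LOW}, \code{MODIFIER} summing to 1, or all-\code{NA} for an empty
#'   set.
#' @examples
#' v <- AnnotatedVariants("1", 1:4, "A", "T", gene = "G",
#'                        impact = c("HIGH", rep("MODERATE", 3)))
#' impactDistribution(v)  # 0.25 0.75 0 0
#' @export
impactDistribution <- function(variants) {
    stopifnot(is(variants, "AnnotatedVariants"))
    if (length(variants) == 0L) {
        return(structure(rep(NA_real_, 4L), names = IMPACT_LEVELS))
    }
    imp <- impactCategory(variants)
    if (anyNA(imp)) {
        stop("variant(s) without impact annotation: ",
             paste(utils::head(variantKey(variants)[is.na(imp)], 3L),
                   collapse = ", "))
    }
    counts <- table(factor(imp, levels = IMPACT_LEVELS))
    structure(as.numeric(counts) / length(variants), names = IMPACT_LEVELS)
}

# interspersed deterministic removal: drop `r` elements from a
# position-ordered index vector, stepping over the survivors
.stepOverRemove <- function(idx, r) {
    drop <- integer(0)
    alive <- idx
    while (r > 0L && length(alive) > 0L) {
        k <- ceiling(length(alive) / r)
        sel <- alive[seq(k, length(alive), by = k)]
        sel <- utils::head(sel, r)
        drop <- c(drop, sel)
        alive <- setdiff(alive, sel)
        r <- r - length(sel)
    }
    drop
}

#' Build an impact-matched benign reference set
#'
#' Constructs the benign comparison set for one gene in three deterministic
#' stages: (1) exclude candidates identical (chrom, pos, ref, alt) to a
#' known pathogenic variant; (2) exclude candidates whose allele frequency
#' exceeds the pathogenic MAF ceiling (absent frequency counts as zero);
#' (3) downsize the remainder to the target impact distribution with a
#' non-random "step over" algorithm that removes interspersed variants, in
#' genomic-position order, from over-represented impact categories. The
#' largest achievable set size is
#' \eqn{n^* = \min_c \lfloor count(c) / target(c) \rfloor} over categories
#' with positive target; categories with target 0 are removed entirely.
#'
#' @param candidates Population \linkS4class{AnnotatedVariants} for the gene.
#' @param knownPatho Known pathogenic variants to exclude by identity.
#' @param mafThreshold Pathogenic allele-frequency ceiling.
#' @param targetDist Target impact distribution (named over
#'   [IMPACT_LEVELS]); typically the pathogenic impact distribution.
#' @param tol Tolerance, as a proportion, on the per-category deviation of
#'   the equalized set from \code{targetDist} (default 0.01, i.e. one
#'   percentage point).
#' @return A list with \code{benign} (the equalized
#'   \linkS4class{AnnotatedVariants}), \code{accounting} (named integer
#'   vector: \code{nCandidates}, \code{removedKnown}, \code{removedAf},
#'   \code{removedStepOver}, \code{nEqualized}; always conserving
#'   \code{nCandidates = nEqualized + removals}), \code{poolDist} (impact
#'   distribution after stages 1-2), \code{mafOnly} (\code{TRUE} when no
#'   benign set could be formed) and \code{withinTolerance}.
#' @export
matchBenignSet <- function(candidates, knownPatho, mafThreshold, targetDist,
                           tol = 0.01) {
    stopifnot(is(candidates, "AnnotatedVariants"))
    if (missing(targetDist) || is.null(targetDist) || all(is.na(targetDist))) {
        stop("matchBenignSet: 'targetDist' is required")
    }
    targetDist <- targetDist[IMPACT_LEVELS]
    n0 <- length(candidates)

    knownKeys <- if (length(knownPatho) > 0L) variantKey(knownPatho)
                 else character(0)
    isKnown <- variantKey(candidates) %in% knownKeys
    s1 <- candidates[!isKnown]

    af <- alleleFreq(s1)
    af[is.na(af)] <- 0
    aboveAf <- af > mafThreshold
    s2 <- s1[!aboveAf]

    acc <- c(nCandidates = n0, removedKnown = sum(isKnown),
             removedAf = sum(aboveAf), removedStepOver = 0L, nEqualized = 0L)
    poolDist <- impactDistribution(s2)

    emptyResult <- function(acc) {
        acc["removedStepOver"] <- length(s2)
        acc["nEqualized"] <- 0L
        list(benign = s2[integer(0)], accounting = acc, poolDist = poolDist,
             mafOnly = TRUE, withinTolerance = FALSE)
    }
    if (length(s2) == 0L) return(emptyResult(acc))

    imp <- impactCategory(s2)
    cnt <- table(factor(imp, levels = IMPACT_LEVELS))
    cnt <- structure(as.integer(cnt), names = IMPACT_LEVELS)
    needed <- names(targetDist)[!is.na(targetDist) & targetDist > 0]
    if (length(needed) == 0L || any(cnt[needed] == 0L)) {
        return(emptyResult(acc))
    }

    nstar <- min(floor(cnt[needed] / targetDist[needed]))
    # integer allocation by largest remainder, capped at availability
    keep <- structure(integer(4), names = IMPACT_LEVELS)
    raw <- nstar * targetDist[needed]
    keep[needed] <- floor(raw)
    rem <- nstar - sum(keep)
    if (rem > 0L) {
        frac <- raw - floor(raw)
        ord <- needed[order(frac, decreasing = TRUE)]
        for (cat in ord) {
            if (rem == 0L) break
            if (keep[cat] < cnt[cat]) {
                keep[cat] <- keep[cat] + 1L
                rem <- rem - 1L
            }
        }
    }

    dropIdx <- integer(0)
    posOrder <- order(as.character(seqnames(s2)), start(s2),
                      mcols(s2)$ref, mcols(s2)$alt)
    for (cat in IMPACT_LEVELS) {
        r <- cnt[cat] - keep[cat]
        if (r <= 0L) next
        idx <- posOrder[imp[posOrder] == cat]
        dropIdx <- c(dropIdx, .stepOverRemove(idx, r))
    }
    keepMask <- !(seq_along(s2) %in% dropIdx)
    benign <- s2[keepMask]

    acc["removedStepOver"] <- length(dropIdx)
    acc["nEqualized"] <- length(benign)
    achieved <- impactDistribution(benign)
    dev <- abs(achieved - ifelse(is.na(targetDist), 0, targetDist))
    list(benign = benign, accounting = acc, poolDist = poolDist,
         mafOnly = FALSE,
         withinTolerance = all(dev <= tol + 1e-12, na.rm = TRUE))
}

#' Calibrate one gene
#'
#' Runs the full per-gene calibration: computes the pathogenic MAF ceiling,
#' builds the impact-matched benign set, derives group mean CADD scores, the
#' 95th percentile sensitivity threshold (type-7 5th percentile of
#' pathogenic CADD scores, exceeded by 95\% of pathogenic variants) and the
#' 95th percentile specificity threshold (type-7 95th percentile of benign
#' CADD scores), performs the Mann-Whitney U test, and assigns exactly one
#' of the seven calibration categories. The decision order is:
#' \code{NOT_CALIBRATED} (fewer than 2 usable variants, or no pathogenic
#' variants), \code{IMPACT_PREDICTIVE} (an impact category present in
#' pathogenic variants but absent from the frequency-matched benign pool;
#' no further CADD calibration), \code{MAF_ONLY} (no benign set could be
#' formed, or no CADD coverage in either group), \code{LITTLE_DATA} (fewer
#' than \code{minN} in either group), \code{ARTIFACT} (significant
#' separation with benign CADD above pathogenic), then
#' \code{CADD_PREDICTIVE} / \code{CADD_LESS_PREDICTIVE} by p value.
#'
#' @param gene Gene symbol.
#' @param patho Pathogenic \linkS4class{AnnotatedVariants} for the gene.
#' @param candidates Population \linkS4class{AnnotatedVariants} for the gene.
#' @param alpha Significance level for the Mann-Whitney test (default 0.05).
#' @param minN Minimum group size for a full CADD calibration (default 5).
#' @param tol Equalization tolerance forwarded to [matchBenignSet()].
#' @return A list with \code{calibration} (one-row data.frame in calibration
#'   table layout), \code{accounting} (stage counts from [matchBenignSet()],
#'   or \code{NULL} when no benign set was attempted) and \code{benign} (the
#'   matched benign set actually used).
#' @export
calibrateGene <- function(gene, patho, candidates, alpha = 0.05, minN = 5L,
                          tol = 0.01) {
    stopifnot(is(patho, "AnnotatedVariants"),
              is(candidates, "AnnotatedVariants"))
    nP <- length(patho)
    nC <- length(candidates)
    row <- data.frame(
        Gene = gene, Category = NA_character_,
        PathoMafThreshold = NA_real_, MeanPathogenicCadd = NA_real_,
        MeanPopulationCadd = NA_real_, Sens95CaddThreshold = NA_real_,
        Spec95CaddThreshold = NA_real_,
        PathogenicImpactDistribution = NA_character_,
        BenignImpactDistribution = NA_character_,
        NPathogenic = nP, NBenign = 0L, MwuPValue = NA_real_,
        stringsAsFactors = FALSE
    )
    done <- function(category, accounting = NULL, benign = NULL) {
        row$Category <- category
        list(calibration = row, accounting = accounting,
             benign = .orElse(benign, patho[integer(0)]))
    }

    if (nP + nC < 2L || nP == 0L) {
        return(done("NOT_CALIBRATED"))
    }

    row$PathoMafThreshold <- pathoMafThreshold(patho)
    pDist <- impactDistribution(patho)
    row$PathogenicImpactDistribution <- .distToString(pDist)

    ms <- matchBenignSet(candidates, patho, row$PathoMafThreshold, pDist,
                         tol = tol)
    poolDist <- ms$poolDist
    poolN <- ms$accounting[["nCandidates"]] -
        ms$accounting[["removedKnown"]] - ms$accounting[["removedAf"]]

    # an impact category seen in pathogenic variants but never in the
    # frequency-matched benign pool is a direct classifier
    if (poolN > 0L &&
        any(pDist > 0 & !is.na(poolDist) & poolDist == 0)) {
        row$BenignImpactDistribution <- .distToString(poolDist)
        row$NBenign <- poolN
        return(done("IMPACT_PREDICTIVE", ms$accounting))
    }

    if (ms$mafOnly) {
        return(done("MAF_ONLY", ms$accounting))
    }

    benign <- ms$benign
    row$BenignImpactDistribution <- .distToString(impactDistribution(benign))
    row$NBenign <- length(benign)

    pCadd <- caddScore(patho)
    pCadd <- pCadd[!is.na(pCadd)]
    bCadd <- caddScore(benign)
    bCadd <- bCadd[!is.na(bCadd)]
    if (length(pCadd) == 0L || length(bCadd) == 0L) {
        row$BenignImpactDistribution <- NA_character_
        row$NBenign <- 0L
        return(done("MAF_ONLY", ms$accounting))
    }

    row$MeanPathogenicCadd <- mean(pCadd)
    row$MeanPopulationCadd <- mean(bCadd)
    row$Sens95CaddThreshold <- percentileR7(pCadd, 0.05)
    row$Spec95CaddThreshold <- percentileR7(bCadd, 0.95)
    mwu <- mannWhitneyU(pCadd, bCadd)
    row$MwuPValue <- mwu$p

    category <-
        if (nP < minN || length(benign) < minN) "LITTLE_DATA"
        else if (mwu$p < alpha &&
                 row$MeanPopulationCadd > row$MeanPathogenicCadd) "ARTIFACT"
        else if (mwu$p < alpha &&
                 row$MeanPathogenicCadd > row$MeanPopulationCadd)
            "CADD_PREDICTIVE"
        else "CADD_LESS_PREDICTIVE"
    done(category, ms$accounting, benign)
}

#' Calibrate all genes of a labelled cohort
#'
#' Splits pathogenic and population variants by gene symbol and calibrates
#' every gene present in the pathogenic set. Per-gene stage accounting is
#' kept in \code{metadata(x)$accounting}.
#'
#' @param patho Pathogenic training variants
#'   (\linkS4class{AnnotatedVariants}).
#' @param population Population candidate variants.
#' @param alpha,minN,tol Forwarded to [calibrateGene()].
#' @return A \linkS4class{GeneCalibrations} object, one row per gene.
#' @export
calibrateGenes <- function(patho, population, alpha = 0.05, minN = 5L,
                           tol = 0.01) {
    stopifnot(is(patho, "AnnotatedVariants"),
              is(population, "AnnotatedVariants"))
    genes <- unique(geneSymbol(patho))
    genes <- genes[!is.na(genes)]
    popGene <- geneSymbol(population)
    rows <- vector("list", length(genes))
    accounting <- vector("list", length(genes))
    names(accounting) <- genes
    for (i in seq_along(genes)) {
        g <- genes[i]
        res <- calibrateGene(
            g, patho[!is.na(geneSymbol(patho)) & geneSymbol(patho) == g],
            population[!is.na(popGene) & popGene == g],
            alpha = alpha, minN = minN, tol = tol
        )
        rows[[i]] <- res$calibration
        accounting[[g]] <- res$accounting
    }
    out <- GeneCalibrations(do.call(rbind, rows))
    metadata(out)$accounting <- accounting
    out
}

#' Genome-wide fallback thresholds
#'
#' The fixed fallback used when gene-specific rules are unavailable or fail
#' to classify: a CADD threshold of 15 (below benign, above pathogenic) and
#' a MAF threshold equal to the arithmetic mean of all gene-specific
#' pathogenic 95th percentile MAF ceilings.
#'
#' @param calibrations A \linkS4class{GeneCalibrations} object with at least
#'   one non-missing \code{PathoMafThreshold}.
#' @return A list with \code{cadd} (always 15) and \code{maf}.
#' @export
genomeWideDefaults <- function(calibrations) {
    stopifnot(is(calibrations, "GeneCalibrations"))
    thr <- calibrations$PathoMafThreshold
    thr <- thr[!is.na(thr)]
    if (length(thr) == 0L) {
        stop("genomeWideDefaults: no gene has a pathogenic MAF threshold")
    }
    list(cadd = 15, maf = mean(thr))
}

#' Shift calibrated thresholds towards sensitivity
#'
#' Relaxes gene-specific thresholds by a single non-negative \code{setting}
#' so that downstream classification favours sensitivity over specificity:
#' the pathogenic MAF ceiling is multiplied by \code{1 + setting} (fewer
#' frequency-based benign calls) and the sensitivity CADD threshold is
#' lowered by \code{setting} points (more pathogenic calls). A setting of 0
#' is the identity; the default of 5 mirrors diagnostic practice where
#' missing a pathogenic variant costs more than a false positive. The
#' classifier floors the effective pathogenic CADD bound at the specificity
#' threshold, so relaxation is monotone: a larger setting never produces
#' fewer pathogenic calls.
#'
#' @param cal A \linkS4class{GeneCalibrations} object (all rows adjusted).
#' @param setting Non-negative relaxation amount (default 5).
#' @return A copy of \code{cal} with adjusted thresholds.
#' @export
applySensitivityAdjustment <- function(cal, setting = 5) {
    stopifnot(is(cal, "GeneCalibrations"))
    if (!is.numeric(setting) || length(setting) != 1L || is.na(setting) ||
        setting < 0) {
        stop("applySensitivityAdjustment: 'setting' must be >= 0")
    }
    if (setting == 0) return(cal)
    df <- as(cal, "DFrame")
    df$PathoMafThreshold <- df$PathoMafThreshold * (1 + setting)
    df$Sens95CaddThreshold <- df$Sens95CaddThreshold - setting
    out <- new("GeneCalibrations", df)
    metadata(out) <- metadata(cal)
    out
}
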