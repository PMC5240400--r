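# Rule-cascade classification of annotated variants.

.VERDICTS <- c("Benign", "Pathogenic", "VUS")

.judgment <- function(verdict, source, rule, reason) {
    list(verdict = verdict, source = source, rule = rule, reason = reason)
}

# classify one variant; cal is the (setting-adjusted) calibration row as a
# list from calibrationFor(), or NULL
.classifyOne <- function(impact, cadd, af, cal, defaults, fallback = TRUE,
                         fallbackOnVus = FALSE) {
    af0 <- if (is.na(af)) 0 else af

    if (!is.null(cal)) {
        # (1) gene-specific MAF dominance
        mafThr <- cal$PathoMafThreshold
        if (!is.na(mafThr) && af0 > mafThr) {
            return(.judgment("Benign", "GENE_SPECIFIC", "MAF_ABOVE_THRESHOLD",
                sprintf("allele frequency %.3g above gene threshold %.3g",
                        af0, mafThr)))
        }
        # (2) impact as a direct classifier
        if (cal$Category == "IMPACT_PREDICTIVE" && !is.na(impact)) {
            pDist <- cal$PathogenicImpactDistribution
            bDist <- cal$BenignImpactDistribution
            unique <- names(pDist)[pDist > 0 & !is.na(bDist) & bDist == 0]
            observed <- names(pDist)[pDist > 0]
            rank <- .impactRank(impact)
            if (length(unique) > 0L && rank >= min(.impactRank(unique))) {
                return(.judgment("Pathogenic", "GENE_SPECIFIC",
                    "IMPACT_DIRECT",
                    sprintf("impact %s unique to pathogenic variants",
                            impact)))
            }
            if (length(observed) > 0L && rank < min(.impactRank(observed))) {
                return(.judgment("Benign", "GENE_SPECIFIC",
                    "IMPACT_BELOW_PATHOGENIC",
                    sprintf("impact %s below all pathogenic impacts",
                            impact)))
            }
        }
        # (3) gene-specific CADD bounds
        caddCats <- c("CADD_PREDICTIVE", "CADD_LESS_PREDICTIVE", "LITTLE_DATA")
        if (cal$Category %in% caddCats &&
            !is.na(cal$Sens95CaddThreshold) &&
            !is.na(cal$Spec95CaddThreshold) && !is.na(cadd)) {
            pBound <- max(cal$Spec95CaddThreshold, cal$Sens95CaddThreshold)
            if (cadd >= pBound) {
                return(.judgment("Pathogenic", "GENE_SPECIFIC",
                    "CADD_ABOVE_SENS95",
                    sprintf("CADD %.2f at or above gene bound %.2f",
                            cadd, pBound)))
            }
            if (cadd <= cal$Spec95CaddThreshold) {
                return(.judgment("Benign", "GENE_SPECIFIC",
                    "CADD_BELOW_SPEC95",
                    sprintf("CADD %.2f at or below benign bound %.2f",
                            cadd, cal$Spec95CaddThreshold)))
            }
            if (!fallbackOnVus) {
                return(.judgment("VUS", "GENE_SPECIFIC",
                    "CADD_BETWEEN_BOUNDS",
                    sprintf("CADD %.2f between gene bounds", cadd)))
            }
        }
    }

    # (4) genome-wide fallback
    if (!fallback) {
        return(.judgment("VUS", "GENOME_WIDE", "NO_FALLBACK",
                         "fallback disabled and gene rules inconclusive"))
    }
    if (af0 > defaults$maf) {
        return(.judgment("Benign", "GENOME_WIDE", "FALLBACK_MAF",
            sprintf("allele frequency %.3g above genome-wide threshold %.3g",
                    af0, defaults$maf)))
    }
    if (!is.na(cadd)) {
        if (cadd > defaults$cadd) {
            return(.judgment("Pathogenic", "GENOME_WIDE", "FALLBACK_CADD",
                sprintf("CADD %.2f above genome-wide threshold %g",
                        cadd, defaults$cadd)))
        }
        return(.judgment("Benign", "GENOME_WIDE", "FALLBACK_CADD",
            sprintf("CADD %.2f at or below genome-wide threshold %g",
                    cadd, defaults$cadd)))
    }
    .judgment("VUS", "GENOME_WIDE", "NO_EVIDENCE",
              "no CADD score and frequency not above threshold")
}

#' Classify annotated variants
#'
#' Applies the gene-aware rule cascade to every variant: (1) an allele
#' frequency above the (sensitivity-adjusted) gene-specific pathogenic MAF
#' ceiling is Benign; (2) for impact-predictive genes, an impact at or above
#' the least severe pathogenic-unique category is Pathogenic and an impact
#' below every pathogenic-observed category is Benign; (3) for genes with
#' CADD bounds, a score at or above the pathogenic bound (the adjusted
#' sensitivity threshold, floored at the specificity threshold) is
#' Pathogenic, at or below the specificity threshold Benign, and in between
#' VUS; (4) otherwise the genome-wide fallback applies: frequency above the
#' fallback MAF threshold is Benign, CADD above 15 Pathogenic, at or below
#' 15 Benign (the boundary is assigned to benign), and with no CADD the
#' variant remains a VUS. Missing annotations degrade to VUS, never to an
#' error, so classification is total and deterministic.
#'
#' @param variants An \linkS4class{AnnotatedVariants} object.
#' @param calibrations A \linkS4class{GeneCalibrations} object, or
#'   \code{NULL} for pure genome-wide classification.
#' @param defaults Genome-wide fallback thresholds, a list with \code{cadd}
#'   and \code{maf} (see [genomeWideDefaults()]).
#' @param setting Sensitivity-adjustment setting applied to
#'   \code{calibrations} before use (default 5; see
#'   [applySensitivityAdjustment()]).
#' @param fallback Set \code{FALSE} to disable genome-wide fallback rules
#'   (inconclusive variants become VUS).
#' @param fallbackOnVus Route the gene-specific "between CADD bounds" zone
#'   to the genome-wide fallback instead of VUS.
#' @return A \linkS4class{DataFrame} parallel to \code{variants} with
#'   columns \code{verdict} (\code{Benign}/\code{Pathogenic}/\code{VUS}),
#'   \code{source} (\code{GENE_SPECIFIC}/\code{GENOME_WIDE}), \code{rule}
#'   and \code{reason}.
#' @export
classifyVariants <- function(variants, calibrations = NULL, defaults,
                             setting = 5, fallback = TRUE,
                             fallbackOnVus = FALSE) {
    stopifnot(is(variants, "AnnotatedVariants"))
    stopifnot(is.list(defaults), !is.null(defaults$cadd),
              !is.null(defaults$maf))
    adj <- NULL
    if (!is.null(calibrations)) {
        stopifnot(is(calibrations, "GeneCalibrations"))
        adj <- applySensitivityAdjustment(calibrations, setting)
    }
    n <- length(variants)
    verdict <- character(n); source <- character(n)
    rule <- character(n); reason <- character(n)
    gene <- geneSymbol(variants)
    impact <- impactCategory(variants)
    cadd <- caddScore(variants)
    af <- alleleFreq(variants)
    calCache <- list()
    for (i in seq_len(n)) {
        cal <- NULL
        if (!is.null(adj) && !is.na(gene[i])) {
            if (is.null(calCache[[gene[i]]])) {
                hit <- calibrationFor(adj, gene[i])
                calCache[[gene[i]]] <- if (is.null(hit)) list(absent = TRUE)
                                       else hit
            }
            cal <- calCache[[gene[i]]]
            if (isTRUE(cal$absent)) cal <- NULL
        }
        j <- .classifyOne(impact[i], cadd[i], af[i], cal, defaults,
                          fallback = fallback, fallbackOnVus = fallbackOnVus)
        verdict[i] <- j$verdict; source[i] <- j$source
        rule[i] <- j$rule; reason[i] <- j$reason
    }
    DataFrame(verdict = verdict, source = source, rule = rule,
              reason = reason)
}

#' Classify a VCF file end to end
#'
#' Reads an annotated VCF, classifies every (variant, gene) instance and
#' writes the input back out with one added INFO key holding the verdict,
#' rule code, source and reason. Returns the judgments invisibly together
#' with per-verdict and per-rule summary counts.
#'
#' @param input,output Paths to the input and output VCF files.
#' @param calibrations A \linkS4class{GeneCalibrations} object or the path
#'   of a calibration table TSV.
#' @param defaults Genome-wide fallback thresholds; when \code{NULL},
#'   derived from \code{calibrations} via [genomeWideDefaults()].
#' @param fields INFO key configuration, see [readAnnotatedVcf()].
#' @param infoKey INFO key used for the classification (default
#'   \code{VCLASS}).
#' @param ... Forwarded to [classifyVariants()].
#' @return Invisibly, a list with \code{variants}, \code{judgments},
#'   \code{verdictCounts} and \code{ruleCounts}.
#' @export
classifyVcf <- function(input, output, calibrations, defaults = NULL,
                        fields = vcfFieldDefaults(), infoKey = "VCLASS",
                        ...) {
    if (is.character(calibrations)) {
        calibrations <- readCalibrationTable(calibrations)
    }
    if (is.null(defaults)) defaults <- genomeWideDefaults(calibrations)
    variants <- readAnnotatedVcf(input, fields = fields)
    judgments <- classifyVariants(variants, calibrations, defaults, ...)
    writeClassifiedVcf(variants, judgments, output, fields = fields,
                       infoKey = infoKey)
    invisible(list(
        variants = variants, judgments = judgments,
        verdictCounts = table(factor(judgments$verdict, levels = .VERDICTS)),
        ruleCounts = table(judgments$rule)
    ))
}
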