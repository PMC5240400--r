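#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
NULL

CALIBRATION_COLUMNS <- c(
    "Gene", "Category", "PathoMafThreshold", "MeanPathogenicCadd",
    "MeanPopulationCadd", "Sens95CaddThreshold", "Spec95CaddThreshold",
    "PathogenicImpactDistribution", "BenignImpactDistribution",
    "NPathogenic", "NBenign", "MwuPValue"
)

#' Annotated variants
#'
#' A \linkS4class{GRanges}-derived container holding one row per
#' (variant, gene) instance: a single alternate allele annotated with the
#' gene symbol, SnpEff-style effect impact, scaled CADD score, population
#' allele frequency and an optional truth label. An absent allele frequency
#' (\code{NA}) means "not observed in the population" and is mapped to zero
#' only where calibration or classification demands it, never at I/O level.
#'
#' @slot .  Inherits all \code{GRanges} slots; the metadata columns
#'   \code{ref}, \code{alt}, \code{gene}, \code{impact}, \code{cadd},
#'   \code{af}, \code{label}, \code{significance} are required.
#'
#' @seealso [AnnotatedVariants()] for the constructor,
#'   [readAnnotatedVcf()] to import from VCF.
#' @export
setClass("AnnotatedVariants", contains = "GRanges")

.AV_COLS <- c("ref", "alt", "gene", "impact", "cadd", "af", "label",
              "significance")

setValidity("AnnotatedVariants", function(object) {
    m <- mcols(object)
    missing <- setdiff(.AV_COLS, colnames(m))
    if (length(missing) > 0L) {
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    }
    msg <- character(0)
    bad <- !grepl("^[ACGTN]+$", m$ref)
    if (any(bad)) {
        msg <- c(msg, paste0("ref allele not a plain A/C/G/T/N string at ",
                             sum(bad), " position(s)"))
    }
    bad <- !grepl("^[ACGTN]+$", m$alt)
    if (any(bad)) {
        msg <- c(msg, paste0("alt allele not a plain A/C/G/T/N string ",
                             "(symbolic alleles are rejected) at ",
                             sum(bad), " position(s)"))
    }
    if (any(start(object) < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(!is.na(m$af) & (m$af < 0 | m$af > 1))) {
        msg <- c(msg, "allele frequencies must lie in [0, 1]")
    }
    if (any(!is.na(m$cadd) & !is.finite(m$cadd))) {
        msg <- c(msg, "CADD scores must be finite where present")
    }
    if (any(!is.na(m$impact) & !(m$impact %in% IMPACT_LEVELS))) {
        msg <- c(msg, paste("impact must be one of",
                            paste(IMPACT_LEVELS, collapse = "/")))
    }
    if (any(!is.na(m$label) & !(m$label %in% TRUTH_LABELS))) {
        msg <- c(msg, paste("label must be one of",
                            paste(TRUTH_LABELS, collapse = "/")))
    }
    if (length(msg) > 0L) msg else TRUE
})

#' Construct an AnnotatedVariants object
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer).
#' @param ref,alt Reference / single alternate alleles over A,C,G,T,N.
#' @param gene Gene symbols; \code{NA} when no gene annotation applies.
#' @param impact Effect impact category (see [IMPACT_LEVELS]) or \code{NA}.
#' @param cadd Scaled CADD score or \code{NA}.
#' @param af Population allele frequency in \eqn{[0,1]}; \code{NA} means the
#'   variant was not observed in the population.
#' @param label Optional truth label (\code{BENIGN}, \code{PATHOGENIC},
#'   \code{VUS}) or \code{NA}.
#' @param significance Optional free-text clinical significance string from
#'   which \code{label} was derived.
#' @return An \linkS4class{AnnotatedVariants} object.
#' @examples
#' AnnotatedVariants("1", 100, "A", "T", gene = "MYH7",
#'                   impact = "MODERATE", cadd = 24.1, af = 1e-4)
#' @export
AnnotatedVariants <- function(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              gene = NA_character_, impact = NA_character_,
                              cadd = NA_real_, af = NA_real_,
                              label = NA_character_,
                              significance = NA_character_) {
    n <- length(pos)
    gr <- GRanges(as.character(chrom),
                  IRanges(start = as.integer(pos),
                          width = nchar(as.character(ref))))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        gene = rep_len(as.character(gene), n),
        impact = rep_len(as.character(impact), n),
        cadd = rep_len(as.numeric(cadd), n),
        af = rep_len(as.numeric(af), n),
        label = rep_len(as.character(label), n),
        significance = rep_len(as.character(significance), n)
    )
    new("AnnotatedVariants", gr)
}

#' Gene calibration table
#'
#' A \linkS4class{DFrame}-derived table with one row per calibrated gene:
#' the calibration category, the pathogenic allele-frequency ceiling (95th
#' percentile of pathogenic MAFs), group mean CADD scores, the 95th
#' percentile sensitivity and specificity CADD thresholds, both impact
#' distributions, group sizes and the Mann-Whitney p value. Numeric fields
#' are \code{NA} exactly where the category implies they could not be
#' computed.
#'
#' @seealso [calibrateGenes()], [readCalibrationTable()],
#'   [writeCalibrationTable()].
#' @export
setClass("GeneCalibrations", contains = "DFrame")

setValidity("GeneCalibrations", function(object) {
    missing <- setdiff(CALIBRATION_COLUMNS, colnames(object))
    if (length(missing) > 0L) {
        return(paste("missing column(s):", paste(missing, collapse = ", ")))
    }
    msg <- character(0)
    if (anyDuplicated(object$Gene)) msg <- c(msg, "duplicate gene symbols")
    badcat <- !(object$Category %in% CALIBRATION_CATEGORIES)
    if (any(badcat)) {
        msg <- c(msg, paste("unknown category token(s):",
                            paste(unique(object$Category[badcat]),
                                  collapse = ", ")))
    }
    cp <- object$Category == "CADD_PREDICTIVE"
    if (any(cp & (is.na(object$MwuPValue) | object$MwuPValue >= 0.05 |
                  object$MeanPathogenicCadd <= object$MeanPopulationCadd |
                  object$NPathogenic < 5 | object$NBenign < 5), na.rm = TRUE)) {
        msg <- c(msg, "CADD_PREDICTIVE row violates its invariants")
    }
    cl <- object$Category == "CADD_LESS_PREDICTIVE"
    if (any(cl & (is.na(object$MwuPValue) | object$MwuPValue < 0.05 |
                  object$NPathogenic < 5 | object$NBenign < 5), na.rm = TRUE)) {
        msg <- c(msg, "CADD_LESS_PREDICTIVE row violates its invariants")
    }
    ld <- object$Category == "LITTLE_DATA"
    if (any(ld & !((object$NPathogenic < 5 | object$NBenign < 5) &
                   object$NPathogenic >= 1 & object$NBenign >= 1))) {
        msg <- c(msg, "LITTLE_DATA row violates its invariants")
    }
    ar <- object$Category == "ARTIFACT"
    if (any(ar & (is.na(object$MwuPValue) | object$MwuPValue >= 0.05 |
                  object$MeanPopulationCadd <= object$MeanPathogenicCadd),
            na.rm = TRUE)) {
        msg <- c(msg, "ARTIFACT row violates its invariants")
    }
    if (length(msg) > 0L) msg else TRUE
})

#' Synthetic gene scenario
#'
#' Parameters of one synthetic gene used by the fixture generator: group
#' sizes, truncated-normal CADD score models for the pathogenic and benign
#' groups, allele-frequency spectra (including a point mass at zero for
#' variants absent from the population), impact-category mixes, the number
#' of pathogenic variants planted into the population set, and the
#' calibration category the scenario is designed to produce.
#'
#' @seealso [geneScenario()], [generateGene()], [scenarioPresets()].
#' @export
setClass("GeneScenario", representation(
    gene = "character",
    nPatho = "integer", nBenign = "integer",
    pathoCaddMean = "numeric", pathoCaddSd = "numeric",
    benignCaddMean = "numeric", benignCaddSd = "numeric",
    pathoAfZeroFraction = "numeric",
    pathoAfBounds = "numeric",
    benignAfBounds = "numeric",
    benignAfZeroMass = "numeric",
    pathoImpactProbs = "numeric", benignImpactProbs = "numeric",
    nPlantedOverlap = "integer",
    plantedCategory = "character"
))

setValidity("GeneScenario", function(object) {
    msg <- character(0)
    probOk <- function(p) length(p) == 4L && all(p >= 0) &&
        abs(sum(p) - 1) < 1e-9
    if (object@nPatho > 0 && !probOk(object@pathoImpactProbs)) {
        msg <- c(msg, "pathoImpactProbs must be 4 probabilities summing to 1")
    }
    if (object@nBenign > 0 && !probOk(object@benignImpactProbs)) {
        msg <- c(msg, "benignImpactProbs must be 4 probabilities summing to 1")
    }
    if (object@nPatho < 0 || object@nBenign < 0) {
        msg <- c(msg, "group sizes must be non-negative")
    }
    if (object@pathoCaddSd <= 0 || object@benignCaddSd <= 0) {
        msg <- c(msg, "CADD standard deviations must be positive")
    }
    if (object@pathoAfZeroFraction < 0 || object@pathoAfZeroFraction > 1 ||
        object@benignAfZeroMass < 0 || object@benignAfZeroMass > 1) {
        msg <- c(msg, "zero-mass fractions must lie in [0, 1]")
    }
    if (length(msg) > 0L) msg else TRUE
})
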