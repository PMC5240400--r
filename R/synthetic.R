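# Synthetic variant cohorts with planted statistical structure. CADD
# scores are truncated normal (scores are non-negative by construction),
# benign allele frequencies log-uniform with a point mass at zero; impact
# categories are allocated at exactly the planted proportions so the mix
# is recoverable within 1/n; positions are consecutive integers per gene
# so that the deterministic step-over downsampler has a well-defined order.

#' Construct a synthetic gene scenario
#'
#' Defaults emulate a well-characterized disease gene: 50 pathogenic and
#' 200 population candidate variants, pathogenic CADD centered at 28.4 and
#' benign at 23.1 (truncated normal, sd 4.8), 90\% of pathogenic variants
#' absent from the population and the remainder rare (log-uniform up to
#' 5e-5), a benign frequency spectrum log-uniform over [1e-6, 0.5] with a
#' 10\% point mass at zero, and the impact mixes of a typical
#' missense-dominated disease gene.
#'
#' @param gene Gene symbol.
#' @param nPatho,nBenign Pathogenic / population candidate counts.
#' @param pathoCaddMean,pathoCaddSd,benignCaddMean,benignCaddSd Truncated
#'   normal CADD parameters per group.
#' @param pathoAfZeroFraction Fraction of pathogenic variants absent from
#'   the population (frequency recorded as absent, not 0).
#' @param pathoAfBounds Log-uniform bounds for the remaining pathogenic
#'   frequencies.
#' @param benignAfBounds Log-uniform bounds of the benign spectrum.
#' @param benignAfZeroMass Point mass at zero (absent) for benign variants.
#' @param pathoImpactProbs,benignImpactProbs Impact-mix proportions over
#'   \code{HIGH}, \code{MODERATE}, \code{LOW}, \code{MODIFIER}; variants
#'   are allocated at exactly these proportions (largest remainder,
#'   shuffled order), so a planted mix is recovered within \eqn{1/n}.
#' @param nPlantedOverlap Number of pathogenic variants also planted into
#'   the population set (exercises known-pathogenic exclusion).
#' @param plantedCategory The calibration category the scenario is designed
#'   to produce.
#' @return A \linkS4class{GeneScenario} object.
#' @export
geneScenario <- function(gene, nPatho = 50L, nBenign = 200L,
                         pathoCaddMean = 28.4, pathoCaddSd = 4.8,
                         benignCaddMean = 23.1, benignCaddSd = 4.8,
                         pathoAfZeroFraction = 0.9,
                         pathoAfBounds = c(1e-6, 5e-5),
                         benignAfBounds = c(1e-6, 0.5),
                         benignAfZeroMass = 0.1,
                         pathoImpactProbs = c(22, 315, 70, 0) / 407,
                         benignImpactProbs = c(0.02, 0.2359, 0.3259,
                                               0.4182),
                         nPlantedOverlap = 5L,
                         plantedCategory = "CADD_PREDICTIVE") {
    new("GeneScenario", gene = gene,
        nPatho = as.integer(nPatho), nBenign = as.integer(nBenign),
        pathoCaddMean = pathoCaddMean, pathoCaddSd = pathoCaddSd,
        benignCaddMean = benignCaddMean, benignCaddSd = benignCaddSd,
        pathoAfZeroFraction = pathoAfZeroFraction,
        pathoAfBounds = pathoAfBounds,
        benignAfBounds = benignAfBounds,
        benignAfZeroMass = benignAfZeroMass,
        pathoImpactProbs = pathoImpactProbs,
        benignImpactProbs = benignImpactProbs,
        nPlantedOverlap = as.integer(nPlantedOverlap),
        plantedCategory = plantedCategory)
}

# truncated normal at zero via inverse CDF
.rtruncnorm0 <- function(n, mean, sd) {
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

.rlogunif <- function(n, bounds) {
    10^stats::runif(n, log10(bounds[1L]), log10(bounds[2L]))
}

# impact categories at exactly the planted proportions (largest-remainder
# allocation, shuffled), so a planted mix is recovered within 1/n
.allocImpacts <- function(n, probs) {
    if (n == 0L) return(character(0))
    counts <- floor(n * probs)
    rem <- n - sum(counts)
    if (rem > 0L) {
        frac <- n * probs - counts
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
    }
    sample(rep(IMPACT_LEVELS, counts))
}

.randomAlleles <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    list(ref = ref, alt = unname(alt))
}

#' Generate one synthetic gene
#'
#' Draws pathogenic and population candidate variants for one
#' \linkS4class{GeneScenario}, deterministic under \code{seed}. Pathogenic
#' and population variants occupy consecutive positions on a synthetic
#' contig; \code{nPlantedOverlap} pathogenic variants are copied
#' (unlabelled) into the population set.
#'
#' @param scenario A \linkS4class{GeneScenario}.
#' @param seed Integer seed.
#' @param contig Contig name (default \code{"1"}).
#' @param offset Position offset for the gene's synthetic interval.
#' @return A list with \code{pathogenic} and \code{population}
#'   \linkS4class{AnnotatedVariants}.
#' @export
generateGene <- function(scenario, seed = 1L, contig = "1", offset = 0L) {
    stopifnot(is(scenario, "GeneScenario"))
    validObject(scenario)
    .withSeed(seed, {
        s <- scenario
        nP <- s@nPatho
        nB <- s@nBenign
        pAll <- .randomAlleles(nP)
        patho <- AnnotatedVariants(
            chrom = rep(contig, nP), pos = offset + seq_len(nP),
            ref = pAll$ref, alt = pAll$alt, gene = s@gene,
            impact = .allocImpacts(nP, s@pathoImpactProbs),
            cadd = .rtruncnorm0(nP, s@pathoCaddMean, s@pathoCaddSd),
            af = ifelse(stats::runif(nP) < s@pathoAfZeroFraction, NA_real_,
                        .rlogunif(nP, s@pathoAfBounds)),
            label = "PATHOGENIC", significance = "Pathogenic"
        )
        bAll <- .randomAlleles(nB)
        pop <- AnnotatedVariants(
            chrom = rep(contig, nB), pos = offset + nP + seq_len(nB),
            ref = bAll$ref, alt = bAll$alt, gene = s@gene,
            impact = .allocImpacts(nB, s@benignImpactProbs),
            cadd = .rtruncnorm0(nB, s@benignCaddMean, s@benignCaddSd),
            af = ifelse(stats::runif(nB) < s@benignAfZeroMass, NA_real_,
                        .rlogunif(nB, s@benignAfBounds)),
            label = "BENIGN", significance = NA_character_
        )
        nOv <- min(s@nPlantedOverlap, nP)
        if (nOv > 0L) {
            planted <- patho[seq_len(nOv)]
            mcols(planted)$label <- NA_character_
            mcols(planted)$significance <- NA_character_
            pop <- suppressWarnings(c(pop, planted))
        }
        list(pathogenic = patho, population = pop)
    })
}

#' Generate a synthetic cohort
#'
#' Generates every scenario on a disjoint synthetic interval (one gene per
#' 10 kb) and optionally writes VCF fixtures (pathogenic and population
#' sets) plus a truth TSV consumable by the I/O layer.
#'
#' @param scenarios A list of \linkS4class{GeneScenario} objects with
#'   unique gene symbols.
#' @param seed Integer seed; gene \code{i} uses \code{seed + i - 1}.
#' @param dir Output directory for \code{pathogenic.vcf},
#'   \code{population.vcf} and \code{truth.tsv}; \code{NULL} skips writing.
#' @return A list with \code{pathogenic} and \code{population}
#'   (\linkS4class{AnnotatedVariants}), \code{truth} (data.frame) and, when
#'   written, \code{paths}.
#' @export
generateCohort <- function(scenarios, seed = 1L, dir = NULL) {
    genes <- vapply(scenarios, function(s) s@gene, character(1))
    if (anyDuplicated(genes)) {
        stop("generateCohort: gene symbols must be unique")
    }
    empty <- AnnotatedVariants()
    pathoList <- list(empty)
    popList <- list(empty)
    for (i in seq_along(scenarios)) {
        g <- generateGene(scenarios[[i]], seed = seed + i - 1L,
                          offset = (i - 1L) * 10000L)
        pathoList[[i + 1L]] <- g$pathogenic
        popList[[i + 1L]] <- g$population
    }
    patho <- suppressWarnings(do.call(c, pathoList))
    pop <- suppressWarnings(do.call(c, popList))
    labelled <- suppressWarnings(c(patho, pop[!is.na(truthLabel(pop))]))
    truth <- data.frame(
        chrom = as.character(seqnames(labelled)), pos = start(labelled),
        ref = refAllele(labelled), alt = altAllele(labelled),
        gene = geneSymbol(labelled), label = truthLabel(labelled),
        stringsAsFactors = FALSE
    )
    out <- list(pathogenic = patho, population = pop, truth = truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- list(
            pathogenic = file.path(dir, "pathogenic.vcf"),
            population = file.path(dir, "population.vcf"),
            truth = file.path(dir, "truth.tsv")
        )
        writeAnnotatedVcf(patho, paths$pathogenic)
        writeAnnotatedVcf(pop, paths$population)
        utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        out$paths <- paths
    }
    out
}

#' Named scenario presets
#'
#' One preset per calibration outcome category, each designed so that
#' calibration recovers the planted category, plus a \code{panel} preset
#' bundling scenarios with a gene-to-manifestation map for stratification
#' tests:
#' \describe{
#'   \item{cadd_predictive}{10-point CADD separation (28 vs 18, sd 3),
#'     50/200 variants.}
#'   \item{cadd_less_predictive}{identical CADD distributions.}
#'   \item{little_data}{3 pathogenic variants.}
#'   \item{impact_predictive}{HIGH impact occurs only in pathogenic
#'     variants.}
#'   \item{maf_only}{all population variants too common for the pathogenic
#'     frequency range.}
#'   \item{not_calibrated}{a single variant.}
#'   \item{artifact}{CADD separation in the inverted direction.}
#' }
#'
#' @return A named list; each element is a \linkS4class{GeneScenario},
#'   except \code{panel} which is a list of \code{scenarios} and a
#'   \code{cgd} map.
#' @export
scenarioPresets <- function() {
    # the CADD presets plant their signal in the scores alone: a balanced
    # impact mix shared by both groups and a 30% absent-from-population
    # mass keep the benign pool from ever starving an impact category, so
    # the planted category is decided by the Mann-Whitney test, not by an
    # accidental impact-matching failure
    eq <- c(0.2, 0.5, 0.3, 0)
    list(
        cadd_predictive = geneScenario(
            "SYNP1", nPatho = 50L, nBenign = 200L,
            pathoCaddMean = 28, pathoCaddSd = 3,
            benignCaddMean = 18, benignCaddSd = 3,
            benignAfZeroMass = 0.3,
            pathoImpactProbs = eq, benignImpactProbs = eq,
            plantedCategory = "CADD_PREDICTIVE"),
        cadd_less_predictive = geneScenario(
            "SYNL1", nPatho = 50L, nBenign = 200L,
            pathoCaddMean = 23, pathoCaddSd = 3,
            benignCaddMean = 23, benignCaddSd = 3,
            benignAfZeroMass = 0.3,
            pathoImpactProbs = eq, benignImpactProbs = eq,
            plantedCategory = "CADD_LESS_PREDICTIVE"),
        little_data = geneScenario(
            "SYND1", nPatho = 3L, nBenign = 150L,
            pathoCaddMean = 28, pathoCaddSd = 3,
            benignCaddMean = 18, benignCaddSd = 3,
            benignAfZeroMass = 0.3,
            pathoImpactProbs = eq, benignImpactProbs = eq,
            nPlantedOverlap = 1L, plantedCategory = "LITTLE_DATA"),
        impact_predictive = geneScenario(
            "SYNI1", nPatho = 30L, nBenign = 150L,
            pathoImpactProbs = c(0.5, 0.5, 0, 0),
            benignImpactProbs = c(0, 0.5, 0.4, 0.1),
            plantedCategory = "IMPACT_PREDICTIVE"),
        maf_only = geneScenario(
            "SYNM1", nPatho = 20L, nBenign = 100L,
            pathoAfZeroFraction = 1,
            benignAfBounds = c(0.01, 0.5), benignAfZeroMass = 0,
            pathoImpactProbs = eq, benignImpactProbs = eq,
            nPlantedOverlap = 0L, plantedCategory = "MAF_ONLY"),
        not_calibrated = geneScenario(
            "SYNN1", nPatho = 1L, nBenign = 0L, nPlantedOverlap = 0L,
            pathoImpactProbs = eq, plantedCategory = "NOT_CALIBRATED"),
        artifact = geneScenario(
            "SYNA1", nPatho = 50L, nBenign = 200L,
            pathoCaddMean = 18, pathoCaddSd = 3,
            benignCaddMean = 28, benignCaddSd = 3,
            benignAfZeroMass = 0.3,
            pathoImpactProbs = eq, benignImpactProbs = eq,
            plantedCategory = "ARTIFACT"),
        panel = list(
            scenarios = list(
                geneScenario("PANC1", pathoImpactProbs = eq,
                             benignImpactProbs = eq),
                geneScenario("PANC2", pathoImpactProbs = eq,
                             benignImpactProbs = eq),
                geneScenario("PANR1", pathoImpactProbs = eq,
                             benignImpactProbs = eq),
                geneScenario("PANX1", pathoImpactProbs = eq,
                             benignImpactProbs = eq)
            ),
            cgd = list(
                PANC1 = "Cardiovascular",
                PANC2 = c("Cardiovascular", "Musculoskeletal"),
                PANR1 = "Renal"
            )
        )
    )
}
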