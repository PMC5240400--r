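test_that("pathogenic selection follows the case-insensitive substring rule", {
    sigs <- c("Pathogenic", "Likely pathogenic", "Benign",
              "Likely benign", "Uncertain significance",
              "Conflicting, pathogenic reported")
    v <- mkVariants(6)
    S4Vectors::mcols(v)$significance <- sigs
    kept <- selectPathogenic(v)
    # regex oracle on the same strings
    expect_equal(S4Vectors::mcols(kept)$significance,
                 sigs[grepl("pathogenic", sigs, ignore.case = TRUE)])
    expect_equal(length(selectPathogenic(v[3])), 0L)
    # negation list drops matching strings
    kept2 <- selectPathogenic(v, negations = "conflicting")
    expect_equal(length(kept2), 2L)
})

test_that("pathogenic MAF ceiling maps absent frequencies to zero", {
    v <- mkVariants(10, af = NA_real_)
    expect_equal(pathoMafThreshold(v), 0)

    afs <- c(rep(0, 9), 0.001)
    v <- mkVariants(10, af = afs)
    # h = 9.55 -> x9 + 0.55 * (x10 - x9) = 0.00055
    expect_equal(pathoMafThreshold(v), 0.00055)
    expect_equal(pathoMafThreshold(v), oracleType7(afs, 0.95))

    expect_true(is.na(pathoMafThreshold(mkVariants(0))))
})

test_that("impact distributions are relative proportions", {
    v <- mkVariants(4, impact = c("HIGH", "MODERATE", "MODERATE",
                                  "MODERATE"))
    expect_equal(unname(impactDistribution(v)), c(0.25, 0.75, 0, 0))
    expect_true(all(is.na(impactDistribution(mkVariants(0)))))
    bad <- mkVariants(2, impact = c("HIGH", NA))
    expect_error(impactDistribution(bad), "without impact")
})

test_that("benign matching removes known, common and interspersed variants", {
    target <- c(HIGH = 0.1, MODERATE = 0.6, LOW = 0.3, MODIFIER = 0)
    set.seed(21)
    cand <- mkVariants(400,
                       impact = sample(IMPACT_LEVELS, 400, replace = TRUE,
                                       prob = c(0.05, 0.3, 0.3, 0.35)),
                       af = ifelse(runif(400) < 0.3, NA,
                                   10^runif(400, -6, -0.3)))
    known <- cand[1:15]
    res <- matchBenignSet(cand, known, mafThreshold = 1e-3,
                          targetDist = target)
    acc <- res$accounting
    expect_equal(acc[["nCandidates"]],
                 acc[["nEqualized"]] + acc[["removedKnown"]] +
                 acc[["removedAf"]] + acc[["removedStepOver"]])
    expect_equal(acc[["removedKnown"]], 15)
    achieved <- impactDistribution(res$benign)
    expect_true(all(abs(achieved - target) <= 0.01))
    expect_true(res$withinTolerance)
    expect_equal(unname(achieved["MODIFIER"]), 0)
})

test_that("impossible impact matching is flagged, not approximated", {
    cand <- mkVariants(30, impact = "MODIFIER", af = 1e-5)
    res <- matchBenignSet(cand, mkVariants(0), 1e-3,
                          c(HIGH = 0, MODERATE = 1, LOW = 0, MODIFIER = 0))
    expect_true(res$mafOnly)
    expect_equal(length(res$benign), 0L)
    expect_equal(res$accounting[["nCandidates"]],
                 sum(res$accounting[c("removedKnown", "removedAf",
                                      "removedStepOver")]))
    expect_error(matchBenignSet(cand, mkVariants(0), 1e-3, NULL),
                 "targetDist")
})

test_that("already matched rare candidates need no step-over removals", {
    cand <- mkVariants(40, impact = rep(c("HIGH", "MODERATE"), each = 20),
                       af = 1e-6)
    res <- matchBenignSet(cand, mkVariants(0), 1e-3,
                          c(HIGH = 0.5, MODERATE = 0.5, LOW = 0,
                            MODIFIER = 0))
    expect_equal(res$accounting[["removedStepOver"]], 0)
    expect_equal(length(res$benign), 40L)
})

test_that("stage accounting always sums over randomized fixtures", {
    set.seed(77)
    for (i in 1:40) {
        n <- sample(10:200, 1)
        cand <- mkVariants(n,
                           impact = sample(IMPACT_LEVELS, n, replace = TRUE),
                           af = ifelse(runif(n) < 0.4, NA,
                                       10^runif(n, -6, -0.3)))
        nk <- sample(0:5, 1)
        known <- if (nk > 0) cand[sample(n, nk)] else mkVariants(0)
        target <- as.numeric(rmultinom(1, 20, runif(4))) / 20
        names(target) <- IMPACT_LEVELS
        res <- matchBenignSet(cand, known, 10^runif(1, -5, -1), target)
        acc <- res$accounting
        expect_equal(acc[["nCandidates"]],
                     acc[["nEqualized"]] + acc[["removedKnown"]] +
                     acc[["removedAf"]] + acc[["removedStepOver"]])
    }
})

test_that("planted scenarios calibrate to their intended categories", {
    presets <- scenarioPresets()
    presets$panel <- NULL
    for (name in names(presets)) {
        s <- presets[[name]]
        g <- generateGene(s, seed = 101)
        res <- calibrateGene(s@gene, g$pathogenic, g$population)
        expect_equal(res$calibration$Category, s@plantedCategory,
                     label = paste("category for preset", name))
    }
})

test_that("scarce data and impact-unique genes short-circuit correctly", {
    g <- generateGene(geneScenario("LD", nPatho = 3L, nBenign = 150L,
                                   pathoCaddMean = 28, benignCaddMean = 18,
                                   pathoImpactProbs = c(0.1, 0.6, 0.3, 0),
                                   benignImpactProbs = c(0.1, 0.6, 0.3, 0)),
                      seed = 4)
    res <- calibrateGene("LD", g$pathogenic, g$population)
    expect_equal(res$calibration$Category, "LITTLE_DATA")
    expect_equal(res$calibration$NPathogenic, 3L)
    # scarce genes still receive CADD bounds for classification
    expect_false(is.na(res$calibration$Sens95CaddThreshold))

    g <- generateGene(scenarioPresets()$impact_predictive, seed = 4)
    res <- calibrateGene("SYNI1", g$pathogenic, g$population)
    expect_equal(res$calibration$Category, "IMPACT_PREDICTIVE")
    # no further CADD calibration on impact-predictive genes
    expect_true(is.na(res$calibration$Sens95CaddThreshold))
    expect_true(is.na(res$calibration$MwuPValue))
})

test_that("category assignment is total and partitions the gene set", {
    p <- scenarioPresets()
    coh <- generateCohort(unname(p[names(p) != "panel"]), seed = 2)
    cal <- calibrateGenes(coh$pathogenic, coh$population)
    expect_equal(nrow(cal), 7L)
    expect_true(all(cal$Category %in% CALIBRATION_CATEGORIES))
    cc <- categoryCounts(cal)
    expect_equal(cc$total, nrow(cal))
    expect_equal(sum(cc$counts), nrow(cal))
})

test_that("genome-wide fallback thresholds are 15 and the mean MAF ceiling", {
    cal <- GeneCalibrations(data.frame(
        Gene = c("A", "B", "C"),
        Category = c("MAF_ONLY", "MAF_ONLY", "NOT_CALIBRATED"),
        PathoMafThreshold = c(0.002, 0.006, NA)))
    def <- genomeWideDefaults(cal)
    expect_equal(def$cadd, 15)
    expect_equal(def$maf, 0.004)

    none <- GeneCalibrations(data.frame(Gene = "A",
                                        Category = "NOT_CALIBRATED",
                                        PathoMafThreshold = NA_real_))
    expect_error(genomeWideDefaults(none), "no gene")
})

test_that("sensitivity adjustment relaxes thresholds monotonically", {
    cal <- GeneCalibrations(data.frame(
        Gene = "G", Category = "LITTLE_DATA", PathoMafThreshold = 1e-4,
        MeanPathogenicCadd = 28, MeanPopulationCadd = 18,
        Sens95CaddThreshold = 20, Spec95CaddThreshold = 15,
        NPathogenic = 3L, NBenign = 10L, MwuPValue = 0.2))
    expect_equal(as.data.frame(applySensitivityAdjustment(cal, 0)),
                 as.data.frame(cal))
    adj <- applySensitivityAdjustment(cal, 5)
    expect_true(adj$Sens95CaddThreshold < 20)
    expect_equal(adj$Sens95CaddThreshold, 15)
    expect_equal(adj$PathoMafThreshold, 6e-4)
    expect_error(applySensitivityAdjustment(cal, -1), ">= 0")
})
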