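test_that("three-outcome metrics follow the missed-inclusive formulas", {
    truth <- c(rep("PATHOGENIC", 10), rep("BENIGN", 10))
    perfect <- c(rep("Pathogenic", 10), rep("Benign", 10))
    sc <- scoreJudgments(truth, perfect)
    expect_equal(sc$sensitivity, 1)
    expect_equal(sc$specificity, 1)
    expect_equal(sc$accuracy, 1)

    verdict <- c(rep("Pathogenic", 8), "Benign", "VUS",
                 rep("Benign", 10))
    sc <- scoreJudgments(truth, verdict)
    expect_equal(sc$counts[["tp"]], 8)
    expect_equal(sc$counts[["fn"]], 1)
    expect_equal(sc$counts[["missedPos"]], 1)
    expect_equal(sc$sensitivity, 0.8)

    expect_error(scoreJudgments(c("VUS"), c("Benign")), "truth labels")
})

test_that("random scoring agrees with the brute-force tally oracle", {
    set.seed(4)
    for (i in 1:10) {
        truth <- sample(c("BENIGN", "PATHOGENIC"), 200, replace = TRUE)
        verdict <- sample(c("Benign", "Pathogenic", "VUS"), 200,
                          replace = TRUE)
        sc <- scoreJudgments(truth, verdict)
        o <- oracleTally(truth, verdict)
        expect_equal(as.list(sc$counts),
                     o[c("tp", "tn", "fp", "fn", "missedPos", "missedNeg")])
        expect_equal(sc$sensitivity, o$sensitivity)
        expect_equal(sc$specificity, o$specificity)
        expect_equal(sc$accuracy, o$accuracy)
        # count conservation against truth-class sizes
        expect_equal(sc$counts[["tp"]] + sc$counts[["fn"]] +
                     sc$counts[["missedPos"]], sum(truth == "PATHOGENIC"))
        expect_equal(sc$counts[["tn"]] + sc$counts[["fp"]] +
                     sc$counts[["missedNeg"]], sum(truth == "BENIGN"))
    }
})

test_that("predictive values use classified-only denominators", {
    pv <- predictiveValues(c(tp = 48, fp = 2, tn = 94, fn = 6,
                             missedPos = 100, missedNeg = 100))
    expect_equal(pv$ppv, 0.96)
    expect_equal(pv$npv, 0.94)
    pv <- predictiveValues(c(tp = 0, fp = 0, tn = 0, fn = 0,
                             missedPos = 5, missedNeg = 5))
    expect_true(is.na(pv$ppv) && is.na(pv$npv))
})

test_that("panel stratification deduplicates within panels", {
    cgd <- list(G1 = c("Cardiovascular", "Musculoskeletal"),
                G2 = "Cardiovascular", G3 = "Renal")
    # one variant in G1; one variant spanning G1 and G2 (two instances,
    # same key); one in an unmapped gene
    v <- AnnotatedVariants("1", c(1, 2, 2, 3), rep("A", 4), rep("T", 4),
                           gene = c("G1", "G1", "G2", "GX"),
                           impact = "MODERATE")
    strata <- stratifyByPanel(v, cgd)
    keysOf <- function(p) variantKey(v)[strata[[p]]]
    expect_setequal(keysOf("Cardiovascular"), c("1:1:A:T", "1:2:A:T"))
    # shared panel: the spanning variant appears exactly once
    expect_equal(sum(keysOf("Cardiovascular") == "1:2:A:T"), 1L)
    expect_setequal(keysOf("Musculoskeletal"), c("1:1:A:T", "1:2:A:T"))
    expect_equal(keysOf("NotInCGD"), "1:3:A:T")
    expect_null(strata[["Renal"]])
})

test_that("a 50-variant stratification matches a hand-built oracle", {
    set.seed(11)
    cgd <- list(A = "P1", B = c("P1", "P2"), C = "P2", D = "P3",
                E = c("P2", "P3"))
    genes <- sample(c(names(cgd), "X1", "X2"), 50, replace = TRUE)
    v <- AnnotatedVariants("1", 1:50, "A", "T", gene = genes,
                           impact = "LOW")
    strata <- stratifyByPanel(v, cgd)
    for (p in c("P1", "P2", "P3")) {
        want <- which(vapply(genes, function(g)
            !is.null(cgd[[g]]) && p %in% cgd[[g]], logical(1)))
        expect_equal(strata[[p]], want, label = p, ignore_attr = TRUE)
    }
    expect_equal(strata[["NotInCGD"]], which(genes %in% c("X1", "X2")),
                 ignore_attr = TRUE)
})

test_that("bootstrap of identical classifiers is a tie, and is seeded", {
    coh <- generateCohort(list(geneScenario("BM1", nPatho = 120L,
                                            nBenign = 200L)), seed = 8)
    v <- labelledSet(coh)
    f <- function(variants) {
        ifelse(caddScore(variants) > 23, "Pathogenic", "Benign")
    }
    res <- bootstrapCompare(v, f, f, nSamples = 50, nBenign = 50,
                            nPatho = 50, seed = 42)
    expect_equal(res$medianA, res$medianB)
    expect_equal(res$mwuP, 1)
    res2 <- bootstrapCompare(v, f, f, nSamples = 50, nBenign = 50,
                             nPatho = 50, seed = 42)
    expect_identical(res$accuracyA, res2$accuracyA)

    perfect <- function(variants) {
        ifelse(toupper(truthLabel(variants)) == "PATHOGENIC", "Pathogenic",
               "Benign")
    }
    res <- bootstrapCompare(v, perfect, f, nSamples = 20, nBenign = 30,
                            nPatho = 30, seed = 1)
    expect_true(all(res$accuracyA == 1))

    expect_error(bootstrapCompare(v, f, f, nBenign = 10000),
                 "truth-benign")
})

test_that("a planted 10% advantage shows up as a 0.10 median gap", {
    # classifier a is right on everything; b errs on a fixed 10% subset
    set.seed(3)
    n <- 600
    v <- AnnotatedVariants("1", seq_len(n), "A", "T", gene = "G",
                           impact = "MODERATE", cadd = 20,
                           label = rep(c("BENIGN", "PATHOGENIC"),
                                       each = n / 2))
    truthOf <- function(variants) toupper(truthLabel(variants))
    a <- function(variants) {
        ifelse(truthOf(variants) == "PATHOGENIC", "Pathogenic", "Benign")
    }
    b <- function(variants) {
        right <- a(variants)
        flip <- start(variants) %% 10 == 0   # a fixed 10% of variants
        ifelse(flip, ifelse(right == "Benign", "Pathogenic", "Benign"),
               right)
    }
    res <- bootstrapCompare(v, a, b, nSamples = 400, nBenign = 100,
                            nPatho = 100, seed = 5)
    expect_equal(res$medianA, 1)
    expect_equal(res$medianA - res$medianB, 0.10, tolerance = 0.03)
})

test_that("benchmark reports cover panels and the combined row", {
    coh <- generateCohort(list(geneScenario("RP1", nPatho = 30L,
                                            nBenign = 60L),
                               geneScenario("RP2", nPatho = 30L,
                                            nBenign = 60L)), seed = 6)
    v <- labelledSet(coh)
    cal <- calibrateGenes(coh$pathogenic, coh$population)
    verdicts <- classifyVariants(v, cal, genomeWideDefaults(cal))$verdict
    cgd <- list(RP1 = "Cardiovascular")
    rpt <- benchmarkReport(v, verdicts, cgd)
    expect_setequal(rpt$panel, c("Combined", "Cardiovascular", "NotInCGD"))
    comb <- rpt[rpt$panel == "Combined", ]
    expect_equal(comb$n, length(v))
    expect_equal(comb$tp + comb$fn + comb$missedPos, comb$nPathogenic)
    expect_true(all(rpt$accuracy >= 0 & rpt$accuracy <= 1))
})
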