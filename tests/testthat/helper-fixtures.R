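# In-code fixture builders shared across test files.

mkVariants <- function(n, gene = "G1", impact = "MODERATE", cadd = 20,
                       af = NA_real_, label = NA_character_, pos = NULL,
                       chrom = "1") {
    if (is.null(pos)) pos <- seq_len(n)
    AnnotatedVariants(rep(chrom, n), pos, rep("A", n), rep("T", n),
                      gene = gene, impact = impact, cadd = cadd, af = af,
                      label = label)
}

# a small annotated VCF written line by line, independent of the package's
# own writer
writeFixtureVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
    header <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=1>",
        paste0("##INFO=<ID=ANN,Number=.,Type=String,",
               "Description=\"Functional annotations\">"),
        "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD\">",
        "##INFO=<ID=EXAC_AF,Number=A,Type=Float,Description=\"AF\">",
        "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Sig\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO"), collapse = "\t")
    )
    writeLines(c(header, lines), path)
    path
}

# a cohort of genes whose optimal CADD cutoffs are dispersed; pathogenic
# and benign CADD are planted symmetrically around each gene's cutoff
dispersedCutoffCohort <- function(nGenes = 20L, cutoffLo = 10, cutoffHi = 30,
                                  halfGap = 5, sd = 3, seed = 1L) {
    cutoffs <- seq(cutoffLo, cutoffHi, length.out = nGenes)
    scenarios <- lapply(seq_len(nGenes), function(i) {
        geneScenario(sprintf("DISP%02d", i), nPatho = 50L, nBenign = 200L,
                     pathoCaddMean = cutoffs[i] + halfGap, pathoCaddSd = sd,
                     benignCaddMean = cutoffs[i] - halfGap, benignCaddSd = sd,
                     pathoImpactProbs = c(0.1, 0.6, 0.3, 0),
                     benignImpactProbs = c(0.1, 0.6, 0.3, 0))
    })
    generateCohort(scenarios, seed = seed)
}

# labelled variant set of a cohort (pathogenic + truth-benign population)
labelledSet <- function(cohort) {
    pop <- cohort$population
    suppressWarnings(c(cohort$pathogenic,
                       pop[!is.na(truthLabel(pop))]))
}
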