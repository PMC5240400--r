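test_that("INFO fields map onto the variant model, absent keys stay absent", {
    path <- writeFixtureVcf(c(
        paste0("1\t100\t.\tA\tT\t.\t.\t",
               "ANN=T|missense_variant|MODERATE|MYH7|MYH7;",
               "CADD=24.1;EXAC_AF=0.0001"),
        "1\t200\t.\tC\tG\t.\t.\tANN=G|stop_gained|HIGH|TTN|TTN;CADD=30"
    ))
    v <- readAnnotatedVcf(path)
    expect_equal(length(v), 2L)
    expect_equal(impactCategory(v)[1], "MODERATE")
    expect_equal(caddScore(v)[1], 24.1)
    expect_equal(alleleFreq(v)[1], 1e-4)
    expect_true(is.na(alleleFreq(v)[2]))  # no EXAC_AF key -> absent
    expect_true(is.na(truthLabel(v)[1]))
})

test_that("an annotation naming two genes yields one instance per gene", {
    path <- writeFixtureVcf(paste0(
        "1\t100\t.\tA\tT\t.\t.\t",
        "ANN=T|missense_variant|MODERATE|GENEA|GENEA,",
        "T|stop_gained|HIGH|GENEB|GENEB;CADD=24.1"
    ))
    v <- readAnnotatedVcf(path)
    # manual field split of the two pipe-separated entries
    expect_equal(length(v), 2L)
    expect_setequal(geneSymbol(v), c("GENEA", "GENEB"))
    expect_equal(impactCategory(v)[geneSymbol(v) == "GENEA"], "MODERATE")
    expect_equal(impactCategory(v)[geneSymbol(v) == "GENEB"], "HIGH")
    expect_equal(unique(variantKey(v)), "1:100:A:T")
})

test_that("multi-allelic records expand to one alt allele each", {
    path <- writeFixtureVcf(paste0(
        "1\t300\t.\tG\tA,C\t.\t.\t",
        "ANN=A|missense_variant|MODERATE|G1|G1,",
        "C|synonymous_variant|LOW|G1|G1;CADD=12,7"
    ))
    v <- readAnnotatedVcf(path)
    expect_equal(length(v), 2L)
    expect_setequal(altAllele(v), c("A", "C"))
    expect_equal(caddScore(v)[altAllele(v) == "A"], 12)
    expect_equal(caddScore(v)[altAllele(v) == "C"], 7)
    expect_equal(impactCategory(v)[altAllele(v) == "C"], "LOW")
})

test_that("read-write-read is the identity on all modeled fields", {
    coh <- generateCohort(list(
        geneScenario("RT1", nPatho = 25L, nBenign = 25L,
                     nPlantedOverlap = 0L),
        geneScenario("RT2", nPatho = 0L, nBenign = 10L,
                     nPlantedOverlap = 0L)
    ), seed = 5)
    v1 <- suppressWarnings(c(coh$pathogenic, coh$population))
    p1 <- tempfile(fileext = ".vcf")
    writeAnnotatedVcf(v1, p1)
    v2 <- readAnnotatedVcf(p1)
    p2 <- tempfile(fileext = ".vcf")
    writeAnnotatedVcf(v2, p2)
    v3 <- readAnnotatedVcf(p2)
    cols <- c("chrom", "pos", "ref", "alt", "gene", "impact", "cadd", "af",
              "label")
    ord <- function(df) df[order(df$chrom, df$pos, df$alt, df$gene), cols]
    expect_equal(ord(as.data.frame(v2)), ord(as.data.frame(v3)),
                 ignore_attr = TRUE, tolerance = 1e-6)
    # and the first write already preserved the generated fields
    expect_equal(ord(unique(as.data.frame(v1)[, cols])),
                 ord(as.data.frame(v2)), ignore_attr = TRUE,
                 tolerance = 1e-6)
})

test_that("rejected records are reported, never silently dropped", {
    path <- writeFixtureVcf(c(
        "1\t100\t.\tA\tT\t.\t.\tCADD=10",
        "1\t200\t.\tC\t<DEL>\t.\t.\t.",
        "1\t300\t.\tG\tA\t.\t.\tCADD=12"
    ))
    expect_warning(v <- readAnnotatedVcf(path), "rejected")
    rej <- S4Vectors::metadata(v)$rejected
    expect_equal(nrow(rej), 1L)
    # conservation: instances out + rejects == record instances in
    expect_equal(length(v) + nrow(rej), 3L)
})

test_that("malformed files fail with a line number, bad impacts loudly", {
    bad <- tempfile(fileext = ".vcf")
    writeLines(c("not a vcf", "1\t1\t.\tA\tT\t.\t.\t."), bad)
    expect_error(readAnnotatedVcf(bad), "line 1")

    truncated <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO"), collapse = "\t"),
                 "1\t100\t.\tA"), truncated)
    expect_error(readAnnotatedVcf(truncated), "line 3")

    path <- writeFixtureVcf("1\t1\t.\tA\tT\t.\t.\tANN=T|x|SEVERE|G|G")
    expect_error(readAnnotatedVcf(path), "unknown impact")
})

test_that("classified output carries the verdict INFO key and reads back", {
    coh <- generateCohort(list(geneScenario("CL1", nPatho = 10L,
                                            nBenign = 20L)), seed = 3)
    v <- coh$population
    cal <- calibrateGenes(coh$pathogenic, coh$population)
    j <- classifyVariants(v, cal, genomeWideDefaults(cal))
    out <- tempfile(fileext = ".vcf")
    writeClassifiedVcf(v, j, out)
    lines <- readLines(out)
    expect_true(any(grepl("^##INFO=<ID=VCLASS", lines)))
    expect_true(all(grepl("VCLASS=", lines[!startsWith(lines, "#")])))
    back <- readClassifiedVcf(out)
    expect_equal(back$judgments$verdict, j$verdict)
    expect_equal(back$judgments$rule, j$rule)

    # empty input stays a valid, header-only VCF
    empty <- AnnotatedVariants()
    out2 <- tempfile(fileext = ".vcf")
    writeClassifiedVcf(empty, classifyVariants(empty, cal,
                                               genomeWideDefaults(cal)),
                       out2)
    expect_equal(length(readAnnotatedVcf(out2)), 0L)
})

test_that("calibration tables round-trip and reject bad rows", {
    coh <- generateCohort(list(geneScenario("TB1"), geneScenario("TB2")),
                          seed = 9)
    cal <- calibrateGenes(coh$pathogenic, coh$population)
    path <- tempfile(fileext = ".tsv")
    writeCalibrationTable(cal, path)
    back <- readCalibrationTable(path)
    expect_equal(as.data.frame(back), as.data.frame(cal),
                 tolerance = 1e-12)

    df <- utils::read.delim(path)
    dup <- rbind(df, df[1, ])
    p2 <- tempfile(fileext = ".tsv")
    utils::write.table(dup, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readCalibrationTable(p2), "duplicate")

    df$Category[1] <- "SOMETHING_ELSE"
    p3 <- tempfile(fileext = ".tsv")
    utils::write.table(df, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readCalibrationTable(p3), "unknown category")
})

test_that("gene-to-panel maps parse, trim and merge categories", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("Gene\tManifestation categories",
                 "MYH7\tCardiovascular",
                 "TTN\tCardiovascular; Musculoskeletal",
                 "TTN\tPulmonary",
                 "PKD1\tRenal ;Genitourinary"), path)
    cgd <- readCgd(path)
    expect_equal(cgd$MYH7, "Cardiovascular")
    expect_setequal(cgd$TTN,
                    c("Cardiovascular", "Musculoskeletal", "Pulmonary"))
    expect_setequal(cgd$PKD1, c("Renal", "Genitourinary"))

    writeLines(c("Symbol\tNotes", "MYH7\tx"), path)
    expect_error(readCgd(path), "manifestation")
})
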