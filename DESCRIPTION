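Package: VariantCalibrator
Title: Gene-Specific Calibration of Variant Pathogenicity Thresholds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Calibrates per-gene classification thresholds for clinical
        variant interpretation from labelled pathogenic and population
        variant sets. For every gene it derives a pathogenic allele-frequency
        ceiling (95th percentile, type-7 quantile), builds an impact-matched
        benign reference set with a deterministic step-over downsampler,
        tests CADD score separation with a Mann-Whitney U test, and assigns
        one of seven calibration categories. Variants are then classified as
        Benign, Pathogenic or VUS using the gene-specific rules with a fixed
        genome-wide fallback, and classifier output can be benchmarked with
        three-outcome sensitivity/specificity metrics, stratified by
        organ-system gene panels, and compared by bootstrap resampling.
        Includes a synthetic variant cohort generator with planted
        statistical structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests: testthat (>= 3.0.0), jsonlite, optparse
biocViews: VariantAnnotation, Classification, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
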