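Package: bidirMR
Title: Bidirectional Mendelian Randomization for Adiposity and Physical Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a bidirectional Mendelian-randomization workflow for
    the causal relationship between childhood adiposity and objectively
    measured physical activity: accelerometer count summarisation with
    wear-time validity and intensity cut-points, sex-specific phenotype
    standardisation, weighted allelic score construction from SNP dosages,
    two-stage least squares instrumental-variable estimation with
    weak-instrument diagnostics and the Durbin form of the Durbin-Wu-Hausman
    endogeneity test, GREML estimation of SNP heritability from a genetic
    relationship matrix, split-sample genome-wide prediction-score
    instruments, and inverse-variance-weighted fixed-effects meta-analysis
    with Cochran's Q. A synthetic-cohort generator with a known planted
    causal structure makes every stage testable without access-restricted
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    yaml,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
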