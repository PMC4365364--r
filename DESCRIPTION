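Package: gva
Title: Genetic Vector Analysis for Multi-Marker Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Groups case-control individuals by their full ordered multi-marker
    genotype combination (the "genetic vector") and tests each group with exact,
    hypergeometric-based odds-ratio statistics. Provides genotype encoding for
    SNP and categorical three-state markers, construction of genetic-vector
    group tables from genotype tables or VCF, per-group randomized odds-ratio
    distributions with exact tail thresholds, two-cohort consistency
    stratification, genotype-content (index-matrix) contrast analysis with
    vector cropping, and a seeded synthetic-cohort generator with planted
    effect sizes for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
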