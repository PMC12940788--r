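Package: chsprofiler
Title: Integrated Immune-Molecular Classification of Chondrosarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for an integrated immune-molecular classification of
    chondrosarcoma cohorts. Discovers tumour immunophenotypes from
    immunohistochemistry marker densities by Ward hierarchical clustering
    with ensemble cluster-number selection and bootstrap stability
    assessment; filters multi-caller somatic variant call sets through a
    staged consensus cascade (per-caller quality thresholds, caller
    intersection, pool-of-normals subtraction, post-filtration and
    annotation-based pathogenicity rules) and computes panel tumour
    mutational burden; runs cohort association statistics; fits
    Kaplan-Meier, log-rank, and LASSO-penalized Cox survival models; and
    builds per-patient immunogram profiles. Includes a synthetic cohort
    generator with known ground truth that emulates the statistical
    structure of a real chondrosarcoma study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    cluster,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
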