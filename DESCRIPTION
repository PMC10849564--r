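Package: devtraj
Title: Centroid-Distance Maturation Trajectories and Developmental
    Contrast Statistics for Single-Nucleus Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how single-nucleus transcriptomic cell types mature
    across a developmental age ladder. Implements maturation trajectories as
    monotone-clamped Manhattan distances between per-age centroids and the
    adult centroid in PCA space, with gradual/intermediate/stepwise
    classification; inter- versus intra-group sample-centroid contrasts for
    sex and sensory-mutant comparisons; pseudobulk F-test differential
    expression across ages (devDEGs) with sharing classification, trend
    fitting, clustering, module scores and a refinement score;
    regionalization correlations; soft label-assignment rules with an
    identity-ratio statistic; and a principal-path pseudotime with a
    developmental-delay test. Includes a seeded negative-binomial
    single-nucleus count simulator with known maturation schedules, sex
    effects, region signatures and genotype delays for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
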