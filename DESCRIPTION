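Package: progsim
Title: Simulating Genetic Effects on Disease Susceptibility and Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A liability-threshold simulation framework for studying how
    genetic effects on disease susceptibility relate to effects on
    within-case disease progression (disease-specific mortality).
    Generates cohorts in which susceptibility and progression share
    genetic variants and a nongenetic risk factor, runs fast
    score-test survival and case-control genome-wide scans, quantifies
    the index event (collider) bias that case-only analyses induce,
    applies a slope-hunter-style mixture correction to paired summary
    statistics, and provides the comparison statistics used in
    susceptibility-versus-progression studies: direction concordance
    with binomial tests, Bonferroni replication counting, polygenic
    score transfer under proportional-hazards models, and
    fixed-effect (inverse-variance and Z-score) meta-analysis with
    Cochran's Q.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
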