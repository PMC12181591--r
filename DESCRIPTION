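Package: cognectome
Title: Group-Level Cognitive Connectome Construction and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level cognitive connectomes from batteries of
    neuropsychological test scores, characterises them with global
    graph-theoretical measures (network strength, global and local
    efficiency, modularity, small-worldness) across a proportional density
    sweep, and compares age and cognitive-reserve groups with non-parametric
    permutation tests under a density-stability criterion. Includes a
    synthetic-cohort generator with planted modular covariance for
    validating every pipeline stage, cohort preprocessing (eligibility
    screening, cohort z-scoring with score inversion, module composites,
    age by reserve stratification), and the accompanying two-way MANOVA
    with canonical discriminant functions on module composites.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    MASS,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
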