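Package: modfc
Title: Modulewise Functional Connectivity Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage pipeline for comparing resting-state functional
    connectivity between two subject groups over a node-and-module brain
    parcellation. Nodes are assigned to canonical resting-state networks by
    winner-take-all over z-statistic maps; per-subject node time series are
    summarized by singular value decomposition and correlated into full
    signed Pearson connectomes; edges are partitioned into module-module
    blocks whose first principal component yields one coordinate per subject
    and block; groups are compared with Cohen's d and Wilcoxon rank-sum
    tests, with an edgewise directional-consistency screen stratified by
    connectivity sign; a linear support vector machine classifies subjects
    from modulewise coordinates and yields dimensional scores; and block
    coordinates are screened for correlation with behavioral measures.
    Includes a block-covariance simulation engine with planted group effects
    for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
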