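Package: pgmpanel
Title: Pharmacogenomic Modelling of Growth Inhibition on Cancer Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for proteochemometric (pharmacogenomic) modelling of compound
    growth-inhibition potency (pGI50) across cancer cell line panels such as the
    NCI60. Curates replicate bioactivity records into a modelling-ready panel,
    assembles cell line profiling "dataset views" (gene subsets, pathway averages,
    ternary copy-number coding), clusters compounds with periodic self-organizing
    maps and U-matrix contouring, encodes cell lines by profiling views or
    similarity kernels (Dirac, multitask, rank-correlation), fits random forest
    and radial-kernel SVM models on concatenated compound-cell line descriptors,
    validates them by interpolation and three extrapolation geometries
    (leave-one-cell-line-, tissue- and compound-cluster-out), attaches conformal
    prediction intervals with an error model and calibration-set non-conformity
    scores, and derives tissue-blocked pathway-drug associations and z-score
    growth-inhibition patterns. A synthetic panel generator with known ground
    truth makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    ranger,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    fgsea,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
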