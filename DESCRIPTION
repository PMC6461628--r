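Package: dynanet
Title: Dynamic Correlation and Bayesian Network Analysis of Inflammatory
    Mediator Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers time-resolved networks from multiplexed inflammatory
    mediator panels measured longitudinally in small cohorts. Implements
    sliding-window signed Pearson correlation networks at a fixed stringency
    threshold ("dynamic network analysis") with a degree-sum network
    complexity statistic, discrete first-order dynamic Bayesian network
    structure learning with bootstrap edge confidence and self-feedback
    central-node detection, a synthetic cohort generator with planted
    network ground truth for end-to-end validation, and a pipeline that
    orchestrates the full analysis from a concentration table to edge lists
    and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: NetworkInference, TimeCourse, GraphAndNetwork, ImmunoOncology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
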