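Package: dmngc
Title: Granger-Causal Hub Analysis of the Default-Mode Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state effective-connectivity analysis of the eight-node
    default-mode network (DMN): temporal preprocessing of ROI BOLD time
    courses, bivariate vector-autoregressive modelling via ordinary least
    squares or Fast Orthogonal Search, Geweke's directed and instantaneous
    Granger-causality measures with IAAFT surrogate significance testing,
    per-subject directed causal graphs with hub degree metrics (the
    D_outer/D_all hub-communication index), group edge-proportion summaries,
    and ROC-based cohort discrimination.  Ships a synthetic-cohort generator
    producing stable VAR processes with known hub-centric causal structure so
    the full pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
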