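Package: netseg
Title: Resting-State Functional Connectivity, System Segregation and
    Graph Metrics for Aging Cohorts
Version: 0.1.0
Authors@R:
    person("netseg", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline from region-of-interest (ROI) resting-state
    BOLD time series to network-level connectivity summaries. Computes
    Fisher z-transformed correlation matrices with diagonal and spatial
    proximity masking, network-wise average positive and negative
    correlations, the system-segregation statistic, and proportionally
    thresholded graph metrics (participation coefficient, local and global
    efficiency, Louvain modularity) on the ten-network 264-ROI functional
    parcellation. Includes age-group ANCOVA-style tests with a scrubbing
    covariate, Bonferroni post hocs, Pearson age and cognition
    correlations, and a synthetic block-covariance cohort generator so the
    whole pipeline is testable without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
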