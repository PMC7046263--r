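Package: schoolphi
Title: Integrated Information Analysis of Small Animal Collectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring information integration in small groups of
    moving animals. Multi-agent trajectories are binarized into collective
    ON/OFF interaction states via distance, visual-field and turning-rate
    rules, a state-by-node transition probability matrix is estimated, and
    IIT 3.0 integrated information (big Phi) is computed with a
    minimum-information-partition search over unidirectional system cuts
    (exhaustive or the cut-one approximation). Mutual information and summed
    pairwise transfer entropy are provided as comparison measures, together
    with leadership detection from single-OFF collective states, parameter
    sweeps over binarization thresholds, a Boids flocking simulator and a
    random Markov-chain baseline for generating synthetic study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
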