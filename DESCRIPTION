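Package: flysleep
Title: Quantitative Two-Phase Analysis of Rest and Sleep in Fly Locomotor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify rest and sleep in Drosophila from continuous
    video recordings. Provides a background-subtraction tracker that recovers a
    fly trajectory from grayscale frame stacks, rest-bout extraction with
    circadian phase labeling, and maximum-likelihood fitting of the two-phase
    bout-duration law in which short rests follow a power-law survival function
    (active index beta) and long rests an exponential one (sleep duration
    lambda), separated by a per-fly sleep latency K located by a
    Kolmogorov-Smirnov changepoint scan. The five parameters (beta, K, lambda,
    N, Total) summarise one fly's sleep architecture per circadian phase. A
    two-hemisphere brain-state random-walk simulator with an exact first-passage
    oracle reproduces the observed pattern, and a synthetic-data generator
    (bout samples, trajectories, rendered frames) makes the whole pipeline
    testable without recordings. Summary tools cover activity and sleep
    profiles, Spearman parameter correlations with hierarchical clustering,
    group comparisons, and sleep-history independence checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
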