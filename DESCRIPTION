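Package: intermove
Title: Analysis of Intermittent Animal Movement: Bouts, Heavy Tails and
    Behavioural Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intermittent locomotion recorded as
    high-frequency planar trajectories in an annular arena. Trajectories
    are discretized into alternating move and pause bouts with per-frame
    rotational (clockwise/anti-clockwise) direction; pause-conditioned
    reorientation is quantified with log-binned turn-probability curves;
    bout-length distributions are fitted by binned maximum likelihood
    under truncated power-law, exponential and power-law-with-
    stretched-exponential-tail models and compared by sequential
    pointwise Akaike weights; move/pause sequence structure is measured
    with partial autocorrelation and cross-correlation against shuffle
    nulls; and behavioural modes (local search vs relocation) are
    segmented with a cumulative partial-sums algorithm. A synthetic
    trajectory generator with a ground-truth bout ledger makes every
    stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
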