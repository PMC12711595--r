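Package: vigilr
Title: Playback-Experiment Vigilance Analysis with Time-Weighted Reaction
    Scoring, Bayesian Crossed-Effects Models and Matched Pseudo-Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing acoustic playback experiments on free-ranging
    wildlife, from raw behavioral event logs to population-level inference.
    Implements one-zero sampling of ethogram-coded behavior at 1-s resolution,
    a 0-12 reaction-intensity index with logistic time-weighting of response
    latencies, Bayesian Gaussian linear mixed models with crossed random
    intercepts (individual, playback event, sound exemplar) fitted by a blocked
    Gibbs sampler, posterior pairwise contrasts within and between study sites,
    Mahalanobis-distance matching of test trials to same-individual controls
    with difference-score models, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    coda,
    withr
Config/testthat/edition: 3
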