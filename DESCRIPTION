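Package: bdmvalue
Title: Subjective Reward Value from Auction Bids and Dopamine-Like Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying trial-by-trial subjective reward value measured
    with Becker-DeGroot-Marschak (BDM) second-price auctions and its neuronal
    correlates. Implements the BDM payoff rules with analytic and numeric
    incentive-compatibility checks; a seeded generator of synthetic bidding
    sessions and dopamine-like two-component spike rasters; behavioral value
    models (lasso variable selection with the one-standard-error rule,
    mixed-effects bid models, rank-order and bid-coherence diagnostics);
    neuronal response analysis (dopamine-like cell classification, value-window
    detection, windowed z-normalized responses, bid regression, matched-bid
    comparisons across reward magnitudes, movement-parameter controls); and
    pseudo-population decoding of bids by linear support vector regression with
    cross-validated, iterated, order-controlled and shuffled-control protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    lme4,
    lmerTest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
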