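Package: madmsg
Title: Multi-Attribute Decision Making for Health Message Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates self-report and psychophysiological message-testing
    data through a multi-attribute decision-making (MADM) pipeline. Scores
    Likert-scale self-report constructs (receptivity, engagement, positive
    attitude, negative emotion), summarizes laboratory signals (heart-rate
    deceleration change scores, recognition-memory hit rates, area-of-interest
    dwell times), assembles a message-by-attribute decision matrix, ranks
    messages within each attribute using competition ranking, evaluates named
    weighting scenarios, and selects consensus messages that perform well
    under every scenario. Ships the published decision matrix for a
    twelve-message waterpipe tobacco risk-communication study as a fixture,
    plus a synthetic-cohort generator for end-to-end testing with planted
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
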