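Package: hardivine
Title: Grapevine Cold Hardiness Modelling from Daily Weather Station Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling dormant-season grapevine bud cold hardiness
    (LT50) from daily weather station records. Reads and curates fixed-width
    GHCNd daily element files, segments records into hemisphere-aware dormant
    seasons, reconstructs hourly temperatures from daily extremes, and builds a
    126-feature predictor set (chilling accumulation under the Utah, North
    Carolina and chill-hours models, growing degree hours at four base
    temperatures, forward and reverse exponentially weighted moving-average
    temperatures, one-hot cultivar indicators). A seeded gradient-boosted
    regressor maps features to LT50, a symmetric logistic converts the gap
    between daily minimum temperature and LT50 into a 0-100 cold-damage
    potential, and climatology helpers summarise seasons, average multi-decade
    windows, grid station values by k-nearest neighbours and score feasible
    cultivation area. A synthetic weather and LT50 generator makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    zoo,
    xgboost,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr
Config/testthat/edition: 3
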