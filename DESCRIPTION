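Package: nanosasa
Title: Machine-Learning Surrogates for Nanoparticle Solvent-Accessible Surface Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening drug-carrier nanoparticle designs by forecasting
    their solvent-accessible surface area (SASA) from a short prefix of a molecular
    dynamics trajectory. Snapshots are encoded as two-body many-body tensor
    representation (MBTR) descriptors, the descriptor trajectory is forecast with a
    per-feature gradient-boosted ensemble (with a scaled-down attention-encoder
    baseline), SASA is regressed from the forecast state with a feed-forward network,
    and predictions are explained per residue via Shapley-style attribution over
    element pairs. Includes a deterministic Shrake-Rupley SASA oracle and a seeded
    generator of synthetic gold-core nanoparticle trajectories so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
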