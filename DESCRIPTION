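Package: ecohorizon
Title: Ecological Forecast Horizons in Time, Space and Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the predictability of ecological systems as forecast
    horizons: the distance in time, space or phylogeny at which forecast
    proficiency crosses a usefulness threshold. Provides proficiency metrics
    (windowed correlation, error metrics, R-squared, similarity indices,
    AUC), horizon estimators with uncertainty distributions, fitted-decay
    horizons and blind-spot detection, Lyapunov-exponent predictability
    times from twin-trajectory divergence, simulators for chaotic Ricker
    population dynamics with parameter uncertainty and for a trait-based
    competitive community with evolution and environmental variability, and
    spatial (distance-decay of community similarity) and phylogenetic
    (host-use prediction sliced by patristic distance) horizon pipelines,
    together with synthetic-data generators for all of them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    minpack.lm,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
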