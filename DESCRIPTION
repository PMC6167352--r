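Package: greensahara
Title: Stochastic Climate-Vegetation Modelling of North African Humid Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An idealised stochastic model of the vegetation-rainfall feedback
    over northern Africa, forced by climatic precession and carbon dioxide
    radiative forcing, for studying the onset and collapse of humid
    ("green Sahara") periods. Provides the forward model with red (AR(1))
    soil-moisture noise, large-ensemble uniform parameter sampling with
    plausibility screening by counting simulated green episodes over the last
    two glacial cycles, an equilibrium-potential analysis yielding per-member
    threshold (tipping) times and a century-binned simulated-sensitivity
    series, dating of humid-period termination from binned proxy state
    compilations, and deterministic synthetic-forcing and ground-truth study
    generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
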