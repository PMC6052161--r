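Package: pondmetab
Title: Whole-Ecosystem Metabolism from Diel Dissolved Oxygen in Ice-Covered Ponds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates whole-ecosystem gross primary production (GPP) and
    ecosystem respiration (ER) from high-frequency dissolved-oxygen time series
    in shallow, seasonally ice-covered ponds. Provides the diel oxygen forward
    model with PAR-apportioned GPP, areal respiration and ice-area-corrected
    air-water gas exchange; Bayesian inversion by random-walk Metropolis MCMC
    with posterior summaries, convergence checks and day-level quality filters;
    gas-exchange physics (oxygen saturation, Schmidt-number scaling, wind-based
    K600); a synthetic-experiment generator emulating a replicated ice-removal
    manipulation; and the treatment-comparison statistics (paired t-tests,
    repeated-measures ANOVA, Pearson correlations) used to analyse such
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
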