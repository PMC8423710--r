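Package: groupsync
Title: Physiological Synchrony in Group Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting physiological synchrony in group-structured
    endocrine time series, such as salivary cortisol and alpha-amylase
    sampled repeatedly around a group stressor. Implements the
    stability-and-influence multilevel growth-curve model (an
    actor-partner interdependence model for directed sender-receiver
    dyads), stepwise model building with likelihood-ratio and AIC
    arbitration, intraclass correlation and variance-partition R2,
    pairwise cross-correlation functions with the conventional
    significance limit, area-under-the-curve-with-respect-to-increase
    summaries, exclusion filters and covariate screening, and a seeded
    synthetic-data generator with known trajectory, stability and
    coupling parameters for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    tibble,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pracma
Config/testthat/edition: 3
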