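Package: pooltrend
Title: Two-Stage Trend Analysis of Organochlorine Pesticides in Pooled
    Human Serum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing temporal trends of organochlorine
    pesticide (OCP) concentrations measured in pooled human serum.
    Implements a two-stage analysis: boosted regression trees screen for
    influential interactions among age group, gender and collection
    period, and Bayesian hierarchical models with random-walk temporal
    effects estimate the selected interaction structures by Gibbs
    sampling.  Includes model assessment (posterior predictive interval
    coverage, DIC, RMSE), posterior trend and percent-change summaries
    with cohort extrapolation, a subsampling sensitivity procedure, a
    synthetic pooled-data generator mirroring the study design, and a
    pipeline driver with delimited-text input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
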