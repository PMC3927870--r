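Package: grnlab
Title: Gene Regulatory Network Simulation, Budgeted In Silico Experiments,
    and Challenge-Style Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for benchmarking parameter estimation and network
    topology inference on gene regulatory network models. Provides a
    declarative model representation with Hill-kinetics transcription and
    translation, deterministic ODE simulation (compiled right-hand sides via
    deSolve), a priced virtual laboratory that sells noisy perturbation
    time-course experiments against a credit budget, challenge scoring
    statistics with resampling null distributions, wisdom-of-crowds
    aggregation of submissions, and a baseline maximum-likelihood estimation
    pipeline with Latin-hypercube multistart fitting, profile-likelihood
    identifiability analysis and prediction-spread experiment ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
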