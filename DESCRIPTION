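Package: wormrisk
Title: Bioaccessibility-Based Probabilistic Health Risk Assessment for
    Medicinal Earthworms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic human health risk assessment of potentially
    toxic elements (Cd, As, Hg, Cu) in medicinal earthworms, driven by
    in-vitro gastrointestinal (PBET) bioaccessibility rather than total
    concentrations.  Provides readers for sample and questionnaire
    tables with QA/QC recovery statistics, bioaccessibility computation
    and per-origin aggregation, maximum-likelihood distribution fitting
    with AIC model selection, a seeded Monte Carlo engine propagating
    exposure-factor uncertainty through estimated daily intake, hazard
    quotient / hazard index and lifetime cancer risk models, Sobol
    variance-based sensitivity analysis (Saltelli design, Jansen
    estimators), and a synthetic-data generator emulating the survey
    and concentration structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    fitdistrplus,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
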