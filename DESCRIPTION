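Package: nanoflow
Title: Dynamic Probabilistic Material-Flow and Ecological Risk Modelling
    for Engineered Nanomaterials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Monte Carlo pipeline for dynamic, cohort-based material-flow
    analysis of engineered nanomaterials (ENMs). Uncertain production
    volumes, market growth trends, application shares and life-cycle
    transfer coefficients are carried as probability distributions and
    propagated through a discrete annual release model (use-phase release,
    in-circulation stock, end-of-life release and waiting stock) over a
    multi-decade horizon. Released masses are partitioned to technical
    sinks and natural compartments, converted to predicted environmental
    concentrations (PECs) under a one-year-degradation and a
    full-persistence scenario, and screened against probabilistic species
    sensitivity distributions (PSSDs) built by resampling ecotoxicological
    endpoints, yielding probabilistic risk percentages for fresh and
    marine waters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
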