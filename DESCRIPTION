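Package: prodmem
Title: Dual-Process Analysis of the Production Effect in Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for dual-process studies of the
    production effect (the memory advantage for words read aloud over words
    read silently). Generates trial-level recognition data from a
    dual-process signal-detection (DPSD) model for remember-know and
    confidence-rating test procedures under within- and between-subject
    designs; estimates recollection and familiarity via the independence
    remember-know procedure and via per-subject DPSD fits to confidence-based
    ROC curves; fits Bayesian multilevel logistic and Gaussian regression
    models (Gibbs sampling via 'rjags') with highest-density-interval
    summaries; derives logit-scale signal-detection metrics (response bias
    C_L and sensitivity d'_L) from logistic coefficients; and synthesizes
    standardized effect sizes (Hedges' g) with Bayesian random-effects
    meta-analysis including a study-design moderator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    lme4
Config/testthat/edition: 3
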