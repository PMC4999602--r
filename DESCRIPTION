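Package: dosenma
Title: Model-Based Network Meta-Analysis with Parametric Dose-Response Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian network meta-analysis of randomized trials comparing
    multiple agents at multiple doses.  Embeds parametric dose-response
    models (Emax, linear, or user-supplied) inside the consistency equations
    of network meta-analysis, so that arm-level binomial data yield coherent
    log-odds-ratio estimates and absolute-response predictions at arbitrary
    doses.  Includes lumped and split network meta-analysis, unrelated
    mean-effects inconsistency models, a separate placebo random-effects
    model for typical-trial prediction, residual-deviance and plug-in DIC
    model criticism, multi-arm random-effects correlation handling,
    Gelman-Rubin diagnostics, and a trial-network simulator with known
    truth.  Models are estimated by Gibbs sampling via JAGS.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
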