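Package: ceaboot
Title: Bootstrap-Based Cost-Effectiveness Analysis with External Evidence
Version: 0.1.0
Authors@R:
    person("ceaboot", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trial-based cost-effectiveness analysis (CEA) by within-arm
    bootstrapping, extended to incorporate external evidence on a log-scale
    effect measure (e.g. a rate ratio) via rejection or importance sampling.
    Bayesian-bootstrap (Dirichlet) or ordinary-bootstrap (scaled multinomial)
    replicates drawn from the no-evidence posterior are reweighted by a
    bounded external likelihood, and the resulting posterior sample is
    summarized as incremental costs and effects, the ICER, credible
    intervals, the cost-effectiveness plane, and the cost-effectiveness
    acceptability curve (CEAC). Includes a synthetic multi-arm trial
    generator, within-replicate missing-data imputation, and two independent
    validation oracles (conjugate normal-normal posterior and exhaustive
    small-sample bootstrap enumeration).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
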