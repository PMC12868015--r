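Package: cryocea
Title: Cost-Effectiveness of Breast Cryoablation Versus Breast-Conserving
    Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Markov cohort cost-effectiveness model comparing
    ultrasound-guided cryoablation with breast-conserving surgery for
    early-stage, low-risk breast cancer over a five-year horizon from a US
    payer perspective.  Provides validated scenario configuration (YAML or
    JSON) with Beta/Gamma/Normal parameter distributions, a discounted
    four-state cohort engine, base-case comparison by net monetary benefit
    and ICER, seeded probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, deterministic one- and
    two-way sweeps, tornado diagrams, and bisection threshold
    (break-even) search, together with tidy() / glance() accessors and
    ggplot2 autoplot() methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
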