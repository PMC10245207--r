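Package: noduletrade
Title: Size-Density Trade-Offs in Termite-Cultivated Fungal Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the size and density of Termitomyces fungal nodules in
    fungus-growing termite nests and tests for size specificity between
    termite farmer castes and their fungal cultivars. Provides a seeded
    synthetic-survey generator emulating a multi-genus field survey, per-nest
    and per-clade trait summaries (sphere volumes, coefficients of variation,
    normality checks), a one-parameter isoquant production-limit model
    L = V x D fitted by closed form, nonlinear least squares and a grid-search
    oracle, one-way ANOVA and log(n+1)-standardised correlation tests, and an
    end-to-end pipeline with CSV/JSON reporting and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
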