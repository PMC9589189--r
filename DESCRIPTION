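Package: orscreen
Title: Odorant-Receptor Library Screening, Dose-Response and Sensory Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heterologous odorant-receptor (OR)
    deorphanization studies: normalization and 2-sigma hit calling of
    cAMP-luminescence library screens, four-parameter Hill concentration-response
    fitting with EC50 summarization and nonresponder calling, internal-standard
    GC-MS quantification of aldehyde emissions with strain fold-ratio
    statistics, triangle-test panel statistics with a genotype-based
    expectation model, and OR haplotype assignment from per-site variant
    calls. Ships a synthetic-data generator emulating the statistical
    structure of each assay so the full pipeline is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
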