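Package: jsdbalance
Title: Jensen-Shannon Divergence Diagnostics for Covariate Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies covariate imbalance across two or more treatment
    groups in comparative clinical studies with the Jensen-Shannon
    divergence (JSD), an information-theoretic statistic measured in bits.
    Provides the entropy and relative-entropy kernel, the JSD balance
    statistic for categorical covariates with its additive decomposition
    into cell, treatment-group and covariate-level contributions,
    histogram-style binning and exact Gaussian quadrature for continuous
    covariates, the standardized difference score for comparison, report
    rendering, a reproducible synthetic-data generator, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    dplyr,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
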