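Package: pcrcal
Title: Calibration-Curve Measurement and Mitigation of PCR Amplification Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Measures and mitigates non-primer-mismatch PCR bias in 16S rRNA
    amplicon count data using calibration curves: a pooled DNA sample is split
    into aliquots amplified for different numbers of PCR cycles, and the
    resulting counts are modelled with a Bayesian multinomial logistic-normal
    log-ratio linear model in which the intercept is the unamplified
    composition and the slope is the per-cycle amplification bias.  Inference
    uses a collapsed matrix-t representation with maximum a posteriori
    estimation, a Laplace approximation, and conjugate recovery of regression
    coefficients and covariance.  Includes compositional-geometry primitives
    (closure, log-ratio transforms, Aitchison distance), count-table
    preprocessing, bias correction of study samples, posterior diagnostics,
    evaluation statistics, and a simulator for calibration experiments.
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    biomformat,
    coda,
    knitr,
    numDeriv,
    optparse,
    rjags,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
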