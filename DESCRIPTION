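Package: taxamix
Title: Negative Binomial and Zero-Inflated Mixed Models for Longitudinal
    Taxa Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits negative binomial mixed models (NBMM), zero-inflated
    negative binomial mixed models (ZINBMM) and zero-inflated Gaussian
    mixed models (ZIGMM) to multilevel or longitudinal microbiome and
    metagenomic abundance tables. Count models are fitted by iteratively
    reweighted least squares on a working linear mixed model with a
    Newton-Raphson dispersion update; zero-inflated models use an
    EM-IWLS algorithm with a logistic (optionally mixed) model for the
    structural-zero part. Includes a many-taxa screening wrapper with
    nonzero-proportion filtering, result summarisation, forest and
    heat-map displays, and a synthetic-data simulator with known truth
    for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
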