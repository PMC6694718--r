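Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An offline toolkit for two-sample Mendelian randomization using
    GWAS summary statistics. Reads and validates summary-statistic tables,
    harmonises exposure and outcome datasets to a common effect allele
    (including strand and palindromic-SNP resolution and LD-proxy
    substitution), selects and clumps instruments, and estimates causal
    effects with the inverse-variance-weighted, MR-Egger, median-based,
    mode-based and maximum-likelihood estimators. Provides the standard
    sensitivity battery (Cochran's Q heterogeneity, Egger intercept
    pleiotropy test, Steiger directionality, leave-one-out, single-SNP,
    funnel and scatter diagnostics), a synthetic two-sample GWAS generator
    with known causal truth, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 3.5)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
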