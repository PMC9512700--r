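Package: rdfit
Title: Two-State Chemical Exchange Analysis of NMR Relaxation Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and global fitting for two-site conformational
    exchange observed by NMR relaxation dispersion. Implements numerical
    Bloch-McConnell propagation of single-quantum and multiple-quantum CPMG
    experiments and of on-resonance R1rho spin-lock experiments, global
    weighted least-squares fitting of multi-probe, multi-field and
    multi-temperature datasets with shared exchange parameters, Monte Carlo
    uncertainty estimation and reduced chi-square surface scans. Auxiliary
    routines cover single-site fluorescence-anisotropy binding fits,
    catalytic turnover rates from time series, derived exchange observables
    and a synthetic-data generator that emulates standard acquisition
    schemes for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
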