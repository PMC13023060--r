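Package: connseg
Title: Surrogate-Thresholded Functional Connectomes and Network Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds surrogate-thresholded, sign-split functional connectomes
    from parcellated BOLD time series and computes intra-, inter- and
    between-network strengths plus a network segregation score over a
    7-network cortical parcellation. Relates these measures to
    depressive-symptom trajectories with cross-sectional regressions and
    two-timepoint repeated-measures interaction designs, including
    Bonferroni and Benjamini-Hochberg corrections, symptom-domain
    decomposition, robustness re-analyses and region-of-interest post-hoc
    drill-down. Ships a synthetic cohort generator with plantable
    connectivity-symptom effects for power and calibration studies, and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
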