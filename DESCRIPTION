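Package: smrconn
Title: Sensorimotor Connectivity and Brain-Computer Interface Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking sensorimotor source-space
    functional connectivity to motor-imagery brain-computer interface (BCI)
    performance. Generates synthetic multi-channel EEG cohorts with planted
    mu-band coupling, event-related desynchronization and 1/f noise on a
    spherical forward model; calibrates common spatial pattern (CSP) plus
    linear discriminant analysis (LDA) classifiers with subject-specific band
    and interval selection; scores simulated online cursor feedback;
    reconstructs region-of-interest source activity with eLORETA and measures
    coupling with the absolute imaginary part of coherency; estimates
    oscillatory signal-to-noise ratio from parametric power-spectrum fits; and
    validates the connectivity-performance association with Spearman and
    partial Spearman correlations, false-discovery-rate correction and
    permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
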