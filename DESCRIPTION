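Package: stresscombo
Title: Bootstrap Additivity Analysis of Combined Abiotic Stresses in
    Split-Plot Pot Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for multifactorial stress-combination pot
    experiments laid out as split plots (e.g. warming as main plots, water
    or salt regime as subplots). Derives resource-use traits from raw
    per-pot measurements, including 15N isotope-dilution fertilizer
    recovery, carbon-isotope discrimination, water- and nitrogen-use
    efficiency; estimates treatment effect sizes as unpaired mean
    differences with bias-corrected and accelerated (BCa) bootstrap
    confidence intervals; computes a bootstrap Additivity Index that
    classifies two-stress interactions as additive, synergistic or
    antagonistic; fits split-plot ANOVA with nested error strata and
    residual diagnostics; and performs canonical discriminant analysis
    with Mahalanobis squared distances between treatment centroids. A
    built-in synthetic-data generator emulates balanced split-plot
    experiments with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
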