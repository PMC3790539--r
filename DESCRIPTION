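Package: camsecr
Title: Multispecies Population Assessment from Camera-Trap Capture-Recapture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit capture-recapture (SECR) density and abundance
    estimation from camera-trap identification records, with half-normal
    detection, sex- and group-level covariates and two-class finite-mixture
    heterogeneity, AICc model selection, and derived home-range summaries.
    Companion tools cover the surrounding assessment workflow: effort-corrected
    capture histories, the two-innate-rates (TIRM) abundance estimator,
    co-detection social-group inference and residency classification, minimum
    convex polygon home ranges with sex-effect models, interobserver
    reliability statistics (Cohen's kappa, exact Wilcoxon signed-rank and
    Friedman tests), and a synthetic camera-trap study generator for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
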