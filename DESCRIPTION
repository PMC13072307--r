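Package: octovm
Title: Longitudinal Corneal Opacity Volume Measurement from Volumetric OCT
Version: 0.1.0
Authors@R:
    person("OVM", "Maintainers", email = "octovm@example.org", role = c("aut", "cre"))
Description: Quantifies corneal scar burden from volumetric optical coherence
    tomography (OCT) scans. Implements the full opacity volume measurement
    (OVM) pipeline: axial motion correction of B-scans, standardized corneal
    button cropping, specular artifact clearing, anterior surface detection,
    surface-referenced flattening, restriction to the anterior stromal field,
    and dual-threshold segmentation separating the corneal button from
    background and hyperreflective (fibrotic) from normal stroma. Includes a
    synthetic phantom generator with analytic ground truth for validation,
    reliability analysis via two-way random-effects absolute-agreement
    intraclass correlation, and the nonparametric statistics used for
    longitudinal group comparison (Kruskal-Wallis with Dunn post hoc,
    Mann-Whitney U, coefficient of variation, sample-size formula).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
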