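Package: liposcreen
Title: High-Content Lipophagy Screening and Nested Case-Control Analytics
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for image-based high-content screening of lipophagy with a
    tandem GFP-mCherry lipid-droplet reporter: synthetic plate/image/flow/
    registry generators with known ground truth, per-well quantification
    (TagBFP nuclei counting, mCherry-mask fluorescence integration, lipophagy
    score), DMSO-plate position correction, robust Z-score hit calling with a
    cell-number toxicity gate, flow-cytometry-style event gating, a nested
    case-control pipeline (cohort filtering, 1:1 caliper matching, 2x2 and
    Mantel-Haenszel tests), and small closed-form assay conversions (HOMA-IR,
    insulin units, fatty-acid oxidation activity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
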