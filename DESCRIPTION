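Package: octquant
Title: Plaque Quantification and Agreement Statistics for Intracoronary OCT Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing and volumetric plaque quantification for multiclass
    segmentations of intracoronary optical coherence tomography (OCT)
    cross-sections. Provides connected-component cleanup of label maps,
    ray casting from the lumen centroid to measure lipid and calcium arcs,
    minimum fibrous cap thickness, calcium depth and thickness, fibrous cap
    area and ratio, lipid-rich-plaque classification and an arc
    correspondence score; frame-wise identification metrics with exact
    binomial confidence intervals, Cohen's kappa, two-way random
    absolute-agreement intraclass correlation, Bland-Altman limits of
    agreement and consensus-frame selection for two-observer external
    testing; and a synthetic vessel-phantom generator with analytically
    known metrics for validation. Label masks are exchanged as indexed PNG
    or uncompressed NIfTI-1 with explicit pixel spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
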