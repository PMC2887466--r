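Package: cytoscreen
Title: Plate Normalization, Local Error Models, and Hit Calling for
    Cell-Based RNAi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for genome-wide, plate-based RNAi screens
    read out by in-cell western (cytoblot) assays. Implements cell-number
    normalization of a phospho-protein signal against a nuclear-fluorescence
    cell-count proxy, per-plate linear regression with pooled residuals, a
    locally weighted cell-number-dependent error model for heteroscedastic
    Z-scoring, plate position-effect correction, source-plate quadrant
    standardization for 384-well plates stamped from four 96-well source
    plates, off-target exclusion, replicate averaging and cutoff-based hit
    calling, plus external standard-curve Z-scoring for follow-up
    experiments. A synthetic screen generator with planted hits and known
    ground truth makes every pipeline stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
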