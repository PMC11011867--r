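Package: pitflux
Title: Intracellular Calcium Responsiveness Analysis for Pituitary Adenoma Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-cell intracellular calcium imaging of
    pituitary adenoma tissue: photobleach correction and dF/Fmin normalization
    of ROI fluorescence time series, high-potassium viability gating, detection
    of spontaneous baseline calcium transients, classification of cells as
    non-, mono- or multi-responsive to hypothalamic secretagogues (CRH, GHRH,
    GnRH, TRH, TRH+DA), tumor-level responsiveness profiles with PCA and
    hierarchical clustering, and a threshold rule linking responsiveness to
    tumor recurrence. Includes a synthetic-recording generator with known
    per-cell ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    broom,
    jsonlite,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
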