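Package: cocultr
Title: Cartesian Plot Quantitation of Fluorescence Transfer in Co-Cultured Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitates transfer of fluorescent label between two co-cultured
    cell populations in fixed monolayers. Per-cell fluorescence is background
    corrected and normalized against control populations cultured alone
    (control median = 100 normalized fluorescence units), each co-cultured
    cell is classified into one of five Cartesian-plot populations relative
    to the control ranges, and transfer is scored on the angular Exchange
    Units scale (-50 to 50). Includes threshold-based two-channel cell and
    nuclear segmentation, cell morphometrics (circularity, profile area),
    normalization of nuclear 5-methylcytosine immunofluorescence against
    propidium iodide and control fibroblasts, nonparametric group
    comparisons, a synthetic data generator with ground truth for
    validation, and table/figure reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
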