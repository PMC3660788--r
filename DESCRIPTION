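Package: flimplate
Title: Time-Gated FLIM-FRET Multiwell Plate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-gated fluorescence lifetime imaging
    (FLIM) plate-reader assays of protein aggregation read out by FRET.
    Provides a synthetic-data generator for gated photon-count image stacks
    with known ground truth, mono- and bi-exponential decay fitting with
    reference reconvolution against a short-lifetime dye standard,
    membrane-selective cell segmentation via a size-tuned nonlinear top-hat
    transform, global-binning estimation of FRETing population fractions,
    and plate-level assay statistics (Z-prime factor, percent inhibition,
    dose-response curves with EC50 estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
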