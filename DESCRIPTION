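Package: photopath
Title: Photosynthetic Pathway Assignment from Plot Surveys and Carbon Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for building continental
    photosynthetic-pathway trait tables from plot-based vegetation surveys
    and bulk-tissue stable carbon isotope analysis. Simulates point-intercept
    plot surveys and isotope-ratio mass spectrometry (IRMS) run sheets,
    normalizes raw delta-13C readings to the VPDB scale by multipoint or
    two-point calibration with drift correction and run-level QC, filters
    herbarium determinations to a unique species list, assigns each species a
    C3, C4 or CAM pathway by literature lookup, genus-level inference or
    delta-13C thresholds, and aggregates point-intercept hits to per-plot
    pathway cover and relative C4 cover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
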