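Package: ivtrace
Title: Intravital Window-Chamber Vascular Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse intravital fluorescence
    microscopy of tumor vasculature in the dorsal window chamber. Aligns
    image stacks by translation, segments the perfused vessel network,
    computes skeleton-based functional vascular density (FVD = L_V/A_T) and
    perfused-vessel diameter (D_V = A_V/L_V) per timepoint, quantifies
    Imax-normalized tracer filling and extravasation (leakage) kinetics, and
    detects vascular-lock duration and leakage onset. Includes a seeded
    synthetic movie generator (vessel networks, tracer pharmacokinetics,
    perfusion scenarios, noise and stage drift) with full ground truth for
    validation, plus Holm-Sidak adjusted group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
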