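Package: nactin
Title: Simulation and Quantification of Calcium-Triggered Nuclear Actin Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying transient nuclear actin assembly (NAA) in
    fluorescence time-lapse microscopy. Provides a stochastic simulator of
    two-channel (actin probe + calcium sensor) nuclear time-lapses with
    Poisson-process filament nucleation, deterministic elongation inside a
    circular nucleus, and Poisson shot-noise rendering; the spatial
    intensity-variance statistic used to score NAA together with range
    normalization, ROI trace extraction and per-cell positive/negative
    scoring; onset detection and calcium-to-NAA lag estimation; and an
    electron-microscopy workflow that classifies nucleus images into four
    chromatin classes and measures the heterochromatin area fraction,
    including a synthetic EM image generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
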