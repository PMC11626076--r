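Package: lungqc
Title: Quantitative Image Quality Assessment for Low-Dose Lung CT
Version: 0.1.0
Authors@R:
    person("lungqc", "maintainers", email = "lungqc@example.org", role = c("aut", "cre"))
Description: Tools for quantifying image quality of low-dose lung computed
    tomography. Edge sharpness is measured as the maximum slope of a
    four-parameter logistic curve fitted to Hounsfield-unit line density
    profiles extracted across lung-to-pleura interfaces with Bresenham
    rasterization, and aggregated to a per-scan median over a configurable
    measurement grid. Supporting metrics include ROI-based signal-to-noise
    and contrast-to-noise ratios, dose estimates (mAs, DLP, effective
    diameter, SSDE, effective dose via user-supplied conversion tables),
    Likert-based diagnostic-quality decisions with ICC(3,k) inter-rater
    reliability, and polynomial dose-response fits. A seeded synthetic
    phantom generator produces CT slices and dose series with known
    ground-truth steepness, compartment HU values and dose-dependent noise,
    so the whole pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
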