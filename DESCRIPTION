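Package: phasensor
Title: Soft-Sensor Calibration of Polyhydroxyalkanoate Concentration from
    Optical Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates, selects, applies, and updates data-driven soft-sensor
    models that estimate intracellular polyhydroxyalkanoate (PHA)
    concentration (g/L) from optical density measurements at 600 nm (OD600).
    A fixed catalog of thirteen candidate regression structures is fitted by
    derivative-free residual-sum-of-squares minimisation with multi-start
    Nelder-Mead search, candidates are ranked by the small-sample corrected
    Akaike information criterion (AICc) and R-squared, predictions carry
    first-order propagated uncertainty, estimation quality is scored by mean
    absolute error, and models can be recalibrated online from lagged,
    up-weighted in-process measurements. A fermentation simulator generates
    batch and fed-batch like OD/PHA trajectories so the whole workflow is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
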