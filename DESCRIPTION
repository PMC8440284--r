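Package: occupet
Title: Occupancy-Plot and Simultaneous Estimation of Non-Displaceable
    Binding in TSPO PET Blocking Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for [11C]PBR28 positron emission
    tomography blocking studies. Builds metabolite-corrected arterial
    plasma input functions from discrete and continuous blood sampling
    (extended Hill fits of the parent plasma fraction and plasma-over-blood
    ratio, multi-exponential whole-blood fits, delay fitting), fits the
    two-tissue compartment model (2TCM) and its vascular-binding extension
    (2TCM1K) to regional time-activity curves by weighted nonlinear least
    squares, estimates drug occupancy and the non-displaceable distribution
    volume V_ND by individual and population-constrained occupancy (Lassen)
    plots, and provides the SIME estimator of a brain-wide V_ND from a
    single baseline scan. Includes a synthetic-data generator emulating a
    seven-subject blocking cohort so the full pipeline is testable without
    access to raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
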