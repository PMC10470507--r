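Package: srmquant
Title: Targeted SRM Quantification of Thiamin and Its Vitamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted LC-MS/MS quantification of vitamin
    B1 (thiamin) and its vitamers (FAMP, AmMP, HMP, cHET, HET) in seawater and
    culture samples by selected reaction monitoring (SRM). Covers chromatogram
    peak integration with linear baseline subtraction, quantifier-transition
    selection by signal-to-noise and blank interference, matrix-matched
    standard-addition calibration with optional heavy-internal-standard
    normalization, blank-based limits of detection and quantification with a
    four-criterion sub-LOQ acceptance rule, spike-based percent-recovery
    correction, and dissolved-phase mass-balance reporting with propagated
    uncertainty. Includes a synthetic SRM-chromatogram generator with a known
    ground-truth ledger so that every stage is verifiable by parameter
    recovery without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
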