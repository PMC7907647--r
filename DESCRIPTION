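Package: hcqpbpk
Title: Whole-Body Physiologically Based Pharmacokinetics of
    Hydroxychloroquine and Desethylhydroxychloroquine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and integrates a whole-body physiologically based
    pharmacokinetic (PBPK) model for hydroxychloroquine (HCQ) coupled to its
    CYP-formed metabolite desethylhydroxychloroquine (DHCQ): transit-chain
    oral absorption, perfusion-limited organ distribution with a
    permeability-limited lung carrying an apparent active-uptake clearance,
    enzyme-resolved hepatic elimination (CYP2C8, CYP2D6, CYP3A4) plus renal
    clearance, and competitive and mechanism-based drug-drug interactions.
    Provides a virtual-population generator (geriatric, hepatic and renal
    impairment, pregnancy, pediatric ontogeny), a virtual clinical-trial
    simulator with baseline-relative exposure ratios, calibration of lung
    uptake to a tissue partition target, weight-based pediatric dose
    matching, and a validation harness (fold-error and prediction-interval
    coverage) with a metabolite clearance fitting routine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
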