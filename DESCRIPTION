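Package: e0703pk
Title: Preclinical-to-Human Pharmacokinetic Extrapolation for the
    Radioprotectant E0703
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental analysis of concentration-time profiles,
    derivation of ADME parameters from in vitro assays (Caco-2 permeability,
    equilibrium-dialysis protein binding, microsomal depletion with
    well-stirred liver scaling, CYP reaction phenotyping), four interspecies
    clearance-scaling methods (simple allometry, single-species scaling,
    two-species scaling, IVIVE), tissue-composition-based prediction of
    tissue-to-plasma partition coefficients and steady-state volume of
    distribution, and a whole-body perfusion-limited physiologically based
    pharmacokinetic (PBPK) model with a compartmental absorption-and-transit
    oral module. Ships the study workflow that calibrates the model on mouse
    and monkey data and predicts human plasma and tissue exposure of the
    radioprotective steroid E0703, evaluated against observed values with
    the conventional 2-fold acceptance window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
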