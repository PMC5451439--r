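Package: gliomafit
Title: Reaction-Diffusion Modelling and Parameter Estimation for Murine Glioma Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward simulation of Fisher-KPP reaction-diffusion tumor growth on
    masked 3D brain domains, Jaccard-distance parameter estimation of the
    diffusion and proliferation rates under three hypotheses about their time
    dependence, identifiability (error-surface) analysis along the constant
    wave-speed arc, and a 2D moving-boundary (Stefan) level-set solver with
    Darcy-law interface velocity. Includes a synthetic phantom generator that
    emulates registered, segmented T2-weighted MR mask series of mouse brains
    so the full pipeline is testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    deSolve,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
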