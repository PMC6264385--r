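Package: qdcm
Title: Quantitative Dual-Calibrated fMRI Mapping of Oxygen Extraction and
    Effective Capillary Oxygen Diffusivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying resting cerebral blood flow (CBF), oxygen
    extraction fraction (OEF), the cerebral metabolic rate of oxygen
    consumption (CMRO2) and the effective oxygen diffusivity of the capillary
    network (Dc) from dual-excitation pCASL/BOLD gas-challenge fMRI.
    Implements a single-capillary oxygen exchange model solved as an ordinary
    differential equation, a lookup table linking CBF and Dc to OEF,
    end-tidal gas trace processing (Severinghaus saturation, arterial oxygen
    content, blood T1), forward signal models for interleaved ASL and BOLD
    timeseries, a regularized voxelwise non-linear least squares fitter,
    task-state CMRO2/OEF/Dc quantification, and a digital phantom generator
    for validation without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
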