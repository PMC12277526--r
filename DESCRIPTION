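Package: alpsdti
Title: Diffusion-Tensor ALPS-Index Analysis of the Glymphatic System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for diffusion-tensor-imaging
    analysis along the perivascular space (DTI-ALPS). Generates template-space
    diffusion-MRI phantoms with known ground-truth perivascular diffusivities
    and Rician measurement noise, fits voxelwise diffusion tensors by weighted
    linear least squares, derives scalar diffusivity maps (FA, MD, AD, RD and
    the tensor diagonal), computes left, right and average ALPS-indices from
    spherical template-space regions of interest, summarises bilateral
    hippocampal diffusion metrics over an atlas label volume, and runs a
    cohort-level statistical chain (assumption-gated omnibus tests with
    FDR-adjusted post hocs, covariate-adjusted linear models, binary logistic
    regression and partial correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    car,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
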