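Package: cedsim
Title: Convection-Enhanced Drug Delivery Simulation Informed by Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxelized finite-volume simulation of convection-enhanced drug
    delivery (CED) in brain tissue. Builds drug transport tensor fields from
    diffusion-MRI-derived water tensors under two microstructure formalisms:
    the classical Gaussian diffusion tensor (D-model) and the displacement
    propagator covariance tensor (R-model), which retains second-order effects
    of restricted and hindered diffusion. Includes a digital brain phantom with
    Gaussian-mixture propagators and two-shell HARDI-like signal synthesis,
    tensor estimation and non-Gaussianity (difference-in-covariances) mapping,
    water-to-drug calibration, a steady anisotropic Darcy pressure solver
    weakly coupled to an implicit advection-diffusion transport solver, and
    analytics that quantify how accounting for diffusion non-Gaussianity
    changes predicted drug distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
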