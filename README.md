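# cedsim

Finite-volume simulation of convection-enhanced drug delivery (CED) in
brain tissue, informed by diffusion MRI — with and without accounting for
diffusion non-Gaussianity.

## The problem

CED infuses a drug directly into brain parenchyma through a catheter under
applied pressure, bypassing the blood–brain barrier. Planning a procedure
requires predicting where the infusate will go, which depends on the
anisotropic, heterogeneous microstructure of the tissue. Classical CED
models map that microstructure with the diffusion tensor (DT) **D**, which
assumes Gaussian water displacement. Water diffusion in tissue is
predominantly *not* Gaussian — molecules are restricted and hindered — and
drug macromolecules feel the same microstructure.

`cedsim` implements two weakly coupled Darcy/advection–diffusion models on
a voxelized mesh whose cells coincide with the imaging voxels:

* **D-model** (classical): `∇·v = 0`, `v = −K ∇p`,
  `φ ∂C/∂t = −∇·(vC) + ∇·(φ D ∇C)`
* **R-model**: identical machinery with `K, D` replaced by `T, R`, where
  **R** is half the covariance of the measured diffusion displacement
  propagator per unit diffusion time,
  `R(r) = (1/2Δ) ∫ P(r|r′,Δ)(r′−r)(r′−r)ᵀ dr′`,
  and **T** is the effective permeability calibrated from it. **R** equals
  **D** exactly when diffusion is Gaussian and otherwise retains the
  second-order restriction/hindrance signature.

Around the two solvers the package provides the full chain a study needs:

* a **digital phantom** (tissue labels, Gaussian-mixture propagators,
  two-shell HARDI-like signals at b = 1200/2400 s/mm², 61 directions per
  shell, 1.2 mm voxels) so everything runs offline with known ground truth;
* **tensor estimation**: log-linear DT fit; covariance tensor from
  ground-truth mixtures or from the exact two-shell quadratic cumulant;
* scalar maps: FA, MD, trace ratio Tr(R)/Tr(D), and **DC** (difference in
  covariances), a non-negative non-Gaussianity measure computed as the
  squared Bures–Wasserstein distance between the Gaussians implied by the
  two tensors (zero iff diffusion is Gaussian at second order);
* **water→drug calibration** by eigenvalue normalization
  (`D_drug = D_cal ξ Λ̄ ξᵀ`, `K_drug = K_cal(tissue) ξ Λ̄ ξᵀ`, …) with
  literature constants (`D_cal = 1e-12`, `K_cal` 100× larger in WM than
  GM, porosity 0.21/0.19 for GM/WM);
* **comparison analytics**: fractional differences f = (C_R − C_D)/C_D,
  5 %-of-max distribution volumes, 3-D Bresenham path sums of DC,
  Pearson correlation of |f| with the path sums, paired t-tests, and
  distribution-volume-vs-infused-volume fits;
* NIfTI/b-table/YAML/JSON I/O and a `cedsim` command-line entry point
  (`inst/cli/cedsim`).

## Worked example

Run the full phantom pipeline — phantom, tensor estimation, calibration,
both CFD models, analytics — on a 20³ phantom with one hour of simulated
infusion into white matter at 1.8 µl/min:

```r
library(cedsim)
cfg <- default_run_config()
cfg$phantom$shape <- c(20, 20, 20)
cfg$solver$t_end  <- 3600        # s
res <- run_pipeline(cfg)
```

Typical output (seed 1):

```
mean FA  D_w: GM 0.000 WM 0.613
mean FA  R_w: GM 0.000 WM 0.633
median Tr(R)/Tr(D): GM 1.12 WM 1.67
mean DC (mm^2): GM 5.12e-07 WM 3.52e-06
V_d at 1 h: R-model 1173.3 mm^3, D-model 1168.1 mm^3
corr(|f|, sum DC): r = 0.28, p = 6.5e-14 (n = 681)
mass ledger closure (R-model): 1.5e-14
```

Reading this: white matter is where diffusion is non-Gaussian, so there
the covariance tensor is more anisotropic (FA 0.633 vs 0.613) and implies
a longer displacement range than the DT fit (trace ratio 1.67 vs 1.12 in
GM); the DC map is an order of magnitude larger in WM than GM. After an
hour of infusion the two models predict similar distribution volumes but
locally different concentrations, and the absolute fractional difference
|f| correlates positively and highly significantly with the DC summed
along the Bresenham line from the catheter voxel — voxels reached through
more non-Gaussian tissue disagree more. The mass ledger (injected vs
in-domain vs out-fluxed volume fraction) closes to machine precision.

The same chain runs from a shell:

```sh
Rscript inst/cli/cedsim all --config demo.yaml --out out/
```

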