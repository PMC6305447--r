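---
title: "Methods: CED transport models, tensor estimation, and the digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CED transport models, tensor estimation, and the digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cedsim)
```

## The two transport models

`cedsim` solves convection-enhanced delivery (CED) as a weakly coupled
system on a voxelized finite-volume mesh. A steady Darcy problem

$$\nabla\cdot v = 0, \qquad v = -\mathsf{K}\,\nabla p$$

fixes the velocity field, and the drug concentration then evolves under

$$\varphi\,\partial_t C = -\nabla\cdot(vC) + \nabla\cdot(\varphi\,\mathsf{D}\,\nabla C),$$

with $\varphi$ the tissue porosity. The *D-model* uses the calibrated
diffusion-tensor pair $(\mathsf{K}_{drug}, \mathsf{D}_{drug})$; the
*R-model* uses $(\mathsf{T}_{drug}, \mathsf{R}_{drug})$ built from the
displacement-covariance tensor

$$\mathsf{R}(r) = \frac{1}{2\Delta}\int_{\mathbb{R}^3}
P(r\,|\,r',\Delta)\,(r'-r)(r'-r)^{\mathsf T}\,dr',$$

i.e. half the covariance of the diffusion propagator per unit diffusion
time. For Gaussian diffusion $\mathsf{R}=\mathsf{D}$ exactly; where
diffusion is restricted or hindered the two differ, and because the
conductivities are calibrated from the same tensors, the difference
propagates into the convective term as well. Both models share one solver;
only the tensor fields differ, so any concentration difference is
attributable to the microstructure formalism.

Assumptions carried over from the underlying modelling tradition: rigid
porous tissue (no poroelastic deformation), no clearance or metabolism, a
point source occupying one mesh cell (no catheter geometry or backflow),
and weak coupling (the pressure field is steady per infusion-rate
segment; concentration does not feed back on the flow).

## Estimating the tensors

* **Diffusion tensor.** Unweighted linear least squares of
  $\log S = \log S_0 - b\,g^{\mathsf T}\mathsf{D}g$ over all volumes of
  both shells; exact for noiseless monoexponential data. A
  signal-squared-weighted variant (`weighted = TRUE`) is available for
  noisy data. Voxels with non-positive signals are flagged and excluded.
* **Covariance tensor.** Two estimators behind one interface:
  `ground_truth` reads the closed-form mixture covariance
  $\sum_i w_i \mathsf{D}_i$ off the phantom; `cumulant` exploits the fact
  that a two-shell protocol determines the quadratic signal model
  $\log S = \log S_0 - b\,a_g + b^2 c_g$ *exactly* per direction, takes
  the $b\to 0$ apparent diffusivity $a_g$ as the directional second
  moment over $2\Delta$, and least-squares fits a symmetric tensor to the
  $\{a_g\}$. Its residual against ground truth is the $O(b^3)$ cumulant
  truncation (measured ≲3 % for two-compartment mixtures at
  b ≤ 2400 s/mm²; the tests bound it at 5 %). A radial-basis-function
  propagator reconstruction would serve the same contract; the exact
  two-shell quadrature was chosen because the protocol has exactly two
  shells, making the estimator closed-form, fast and testable.
* **DC (difference in covariances).** The printed definition of this
  non-Gaussianity measure — the minimal expected squared discrepancy
  $\min \int \lVert\tilde r\rVert^2\,G(r)\,dr$ between the actual and the
  Gaussian displacement — leaves the minimization variable implicit. At
  second order both distributions are zero-mean Gaussians with
  covariances $\Sigma_R = 2\Delta\mathsf{R}$ and
  $\Sigma_D = 2\Delta\mathsf{D}$, and the minimal expected squared
  displacement difference over all couplings of two Gaussians has a
  closed form, the squared Bures–Wasserstein distance
  $$\mathrm{DC} = \operatorname{Tr}\Sigma_R + \operatorname{Tr}\Sigma_D
    - 2\operatorname{Tr}\bigl(\Sigma_D^{1/2}\Sigma_R\Sigma_D^{1/2}\bigr)^{1/2}
    \;\;[\mathrm{mm}^2].$$
  This satisfies every property the measure requires: non-negative, zero
  iff the covariances coincide, monotone in covariance discrepancy. A
  test ties the implementation to a brute-force optimal-coupling oracle
  (numeric optimization over orthogonal transport maps) and to the
  commuting-case closed form $\sum_i(\sqrt{\lambda_i^R}-\sqrt{\lambda_i^D})^2$.

## Calibration

Water tensors set the shape, tissue class sets the magnitude: per voxel
the tensor is eigen-decomposed, eigenvalues are divided by their mean
(so the normalized tensor has trace 3), and the drug tensors are
$D_{cal}\,\xi\bar\Lambda\xi^{\mathsf T}$ (diffusivities) and
$K_{cal}(\text{tissue})\,\xi\bar\Lambda\xi^{\mathsf T}$ (conductivities),
preserving the water eigenvectors exactly. Defaults follow the CED
literature: $D_{cal}=10^{-12}$, $K_{cal}^{WM}=1.3\times10^{-12}$,
$K_{cal}^{GM}=0.013\times10^{-12}$ (interstitial flow up to 100× faster
along white matter), porosity 0.21 (GM) and 0.19 (WM). That literature
does not parameterize CSF; the package treats it as free-fluid-like
(conductivity = WM value, porosity 0.9) to avoid spurious barriers at
ventricle boundaries — an explicitly unvalidated choice, isolated in
`calibration_constants()`. Because the conductivity magnitudes are
calibration-relative, the *fixed-rate* source mode (the clinically
controlled quantity) is primary: velocities are set by the infusion rate
Q through mass conservation and are independent of the conductivity
scale, while the emergent pressure difference is reported as-is. A
fixed-pressure mode (Dirichlet at the source cell, rate emergent) is
provided for scenario matching; with both the rate and a target pressure
difference quoted for a scenario, the linear Darcy problem is
over-determined, so the package never asserts both at once.

## Discretization and numerical choices

* **Mesh.** Cells coincide with voxels (properties assigned per voxel, no
  interpolation); 6-neighbor face connectivity; `refine_mesh()` splits
  each cell into $f^3$ children with piecewise-constant property mapping.
* **Pressure.** Face-normal conductances from arithmetically averaged
  face tensors ($-\kappa_{nn}A\,\Delta p/h$); tensor cross terms
  ($\kappa_{nt}$, tangential gradients from averaged central differences)
  by deferred correction from the previous iterate, keeping the assembled
  matrix 7-point SPD (sparse Cholesky; relative change tolerance
  $10^{-12}$). Boundary faces carry Dirichlet $p=p_b$ at distance $h/2$;
  cross terms are omitted on boundary faces.
* **Transport.** Backward-Euler in time (default dt = 1 s; phantom-scale
  analyses use 5 s), first-order upwind advection on the stored face
  fluxes, implicit face-normal diffusion on $\varphi\mathsf{R}$ (or
  $\varphi\mathsf{D}$), cross-diffusion terms explicit from the previous
  step. The scheme is unconditionally stable, strictly non-oscillatory in
  its implicit part, and conservative by construction: the mass ledger
  (injected vs in-domain vs out-fluxed) closes to solver precision, and
  tests require $10^{-6}$ relative. The trade-off is first-order upwind
  numerical diffusion; a flux-limited explicit scheme was considered and
  rejected to keep the unconditional-stability contract at dt = 1 s.
  Boundary condition: advective outflow with zero diffusive flux —
  conserves the ledger and adds no artificial sinks.
* **Linear solves.** Pressure: sparse Cholesky. Transport: the implicit
  matrix is an M-matrix with positive diagonal, so a diagonal-pivot LU
  with AMD ordering is stable and keeps fill low; factored once per
  (segment, dt) and reused across steps. Direct solves put residuals at
  machine precision, well inside the $10^{-10}$/$10^{-8}$ contracts.
* **Face averaging.** Arithmetic by default; harmonic averaging of
  $\varphi\mathsf{K}$ is available (`face_avg = "harmonic"`) for
  high-contrast interfaces such as the 100× GM/WM conductivity jump.
* **Degenerate inputs.** Near-zero tensors are flagged isotropic-unit in
  eigenvalue normalization; negative eigenvalues are clamped to
  $10^{-12}\times$ the voxel mean before SPD-requiring steps; negative
  directional diffusivities in the cumulant estimator clamp to zero with
  a count; concentrations below $-10^{-10}\,\max C$ abort the run.
* **Eigenvector conventions.** Eigenvalues sorted descending; sign and
  ordering of eigenvectors never matter because only outer products are
  used.

## The digital phantom

The phantom replaces a participant scan so that every stage is testable
offline. It emulates the statistical structure the analysis relies on:

* geometry: ellipsoidal brain, CSF rim, GM shell, an interior WM slab
  whose fiber tangent rotates smoothly in-plane (a bent tract), and an
  embedded 90° crossing region;
* propagators: per-tissue zero-mean Gaussian mixtures — CSF a single
  isotropic Gaussian (2.0×10⁻³ mm²/s); GM a mildly non-Gaussian isotropic
  pair (1.0/0.45×10⁻³, weights 0.85/0.15), keeping the GM trace ratio
  near 1; single-fiber WM a hindered compartment (axial 1.8×10⁻³, radial
  0.35×10⁻³) plus a strongly restricted one (0.30/0.05×10⁻³), weights
  0.6/0.4. Putting the dominant diffusivity contrast along the fiber axis
  concentrates the kurtosis axially, which is what makes the covariance
  tensor *more* anisotropic than the DT fit in WM (FA(R) > FA(D)) while
  keeping DC an order of magnitude larger in WM than GM — the qualitative
  contrasts the comparison analytics assume. The seed drives small
  (±2 %) voxelwise weight/diffusivity jitter; geometry is deterministic.
* signals: multi-tensor forward model
  $S = S_0\sum_i w_i e^{-b\,g^{\mathsf T}\mathsf{D}_i g}$, optional
  Rician noise (noiseless by default); acquisition matches a two-shell
  protocol (b = 1200/2400 s/mm², 61 directions per shell via a spherical
  Fibonacci lattice, 1.2 mm voxels). The effective diffusion time is not
  part of the signal model and must be supplied; the default
  $\Delta = 0.03$ s is typical for pulsed-gradient spin-echo, and every
  $\Delta$-dependent quantity carries it explicitly. Covariance tensors
  are reported in mm²/s (covariance over $2\Delta$) so they are
  commensurate with diffusivities.

What the phantom does **not** emulate: EPI/motion/eddy artifacts, partial
volume, realistic cortical folding, distributed fiber dispersion, or
exchange. Passing tests therefore demonstrate correctness of the
estimators and solvers under the stated mixture model, not robustness to
acquisition artifacts in vivo.

## Analysis conventions

* Fractional difference $f = (C_R - C_D)/C_D$ is reported where
  $C_D \ge 10^{-3}\max C_D$: large enough to exclude numerical zeros,
  small enough to keep the front of the spread, where $|f|$ is largest.
* Distribution volume: voxels reaching ≥5 % of the maximum concentration.
* Path non-Gaussianity: DC summed over the 3-D Bresenham voxel sequence
  from the infusion voxel (driving axis by largest |Δ|, x>y>z on ties) —
  an acknowledged approximation of the fluid path, used as a
  representative measure, not a streamline.
* Correlations (Pearson, two-sided) and the paired t-test are evaluated
  over the distribution volume(s); whole-brain masks would dilute both
  with unreached voxels.
* Rate comparisons at matched infused volume scale the time step
  inversely with the rate (matched Courant number), so the discrete
  advective map is identical across rates and the comparison isolates the
  physical time available for diffusion.
* On refined meshes the source occupies the 8 children of the coarse
  source voxel — the same physical catheter opening — because a
  single-child source would change the maximum concentration and hence
  the 5 %-of-max volume by construction.

## Problem sizes used by the tests

Unit tests run on 12³–16³ phantoms; the solver oracles use a 41³
homogeneous ball (pressure vs the analytic point-source solution
$Q/(4\pi\kappa)(1/r - 1/R)$ for a sphere with Dirichlet boundary), a 25³
grid for the heat-kernel comparison (σ > 3h), and a 24³ closed-domain
mass-balance run of 500 implicit steps. The model-comparison analogue
runs the full pipeline on 32³ phantoms (≈13 000 cells) for 2 simulated
hours at dt = 5 s across 10 seeds, and the grid-convergence check refines
a 16³ phantom to 32³ with dt halved. These sizes were chosen so the whole
suite completes on a laptop-class single core while every check retains
its discriminating power.

## Known limitations

* First-order upwind advection smears sharp fronts; distribution volumes
  converge (the refinement check bounds the change at <10 %) but front
  widths are resolution-dependent.
* The cumulant covariance estimator is exact only through $O(b^2)$;
  strongly restricted compartments bias it toward the DT fit, i.e. DC is
  conservatively *under*-estimated in the most non-Gaussian voxels.
* Calibration constants are literature-scale, not participant-specific;
  reported pressures are calibration-relative in fixed-rate mode.
* No clearance, metabolism, backflow, or tissue deformation.
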