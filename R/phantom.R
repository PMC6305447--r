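# Digital brain phantom: tissue labels, Gaussian-mixture displacement
# propagators, and two-shell HARDI-like diffusion signal synthesis. The
# phantom stands in for a participant scan so that every downstream stage
# (tensor estimation, calibration, CFD, comparison analytics) can be
# exercised offline with known ground truth.

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

LABEL_LEVELS <- c(background = 0L, GM = 1L, WM = 2L, CSF = 3L)

#' Two-shell HARDI-like acquisition scheme
#'
#' Builds a diffusion acquisition with `n_b0` unweighted volumes followed by
#' the same set of `n_dirs` unit directions repeated on every b-shell
#' (default two shells at 1200 and 2400 s/mm2, 61 directions each, matching
#' a high-angular-resolution two-shell protocol). Directions are spread
#' quasi-uniformly on the sphere with a spherical Fibonacci lattice.
#'
#' @param n_dirs number of gradient directions per shell.
#' @param bvals  vector of non-zero b-values, s/mm2.
#' @param n_b0   number of b = 0 volumes.
#' @param delta  effective diffusion time, s. The acquisition does not fix
#'   this by itself; it is carried so that covariance <-> diffusivity
#'   conversions (factor 2*delta) are explicit everywhere.
#' @return object of class `ced_scheme`: list with `b` (per volume),
#'   `dirs` (n_vol x 3 unit vectors, zero rows for b = 0), `n_b0`, `delta`.
#' @export
two_shell_scheme <- function(n_dirs = 61, bvals = c(1200, 2400), n_b0 = 1,
                             delta = 0.03) {
  stopifnot(n_dirs >= 6, all(bvals > 0), n_b0 >= 1, delta > 0)
  dirs <- fibonacci_sphere(n_dirs)
  b <- c(rep(0, n_b0), rep(bvals, each = n_dirs))
  g <- rbind(matrix(0, n_b0, 3), dirs[rep(seq_len(n_dirs), length(bvals)), ])
  structure(list(b = b, dirs = g, n_b0 = n_b0, delta = delta,
                 n_dirs = n_dirs, bvals = bvals),
            class = "ced_scheme")
}

# quasi-uniform unit vectors on the sphere (spherical Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(phi), r * sin(phi), z)
  m / sqrt(rowSums(m^2))
}

#' Generate a phantom tissue label map
#'
#' Deterministic (per seed) synthetic segmentation with the compartments a
#' brain segmentation would provide: an ellipsoidal brain with a CSF rim, a
#' gray-matter shell, an interior white-matter slab carrying a bent fiber
#' tract, and an embedded fiber-crossing region. The `wm_zone` attribute
#' distinguishes single-fiber from crossing white matter for the propagator
#' generator.
#'
#' @param shape integer length-3 grid size; every axis must be at least 12
#'   for the default preset (8 for single-compartment presets).
#' @param preset `"default"` (all four labels), `"uniform_gm"` or
#'   `"uniform_wm"` (ellipsoidal mask of a single tissue).
#' @param voxel_size isotropic voxel edge, mm (default 1.2).
#' @param seed integer seed controlling the small stochastic perturbations
#'   of the tissue recipe downstream; the geometry itself is deterministic.
#' @return object of class `ced_labels`: list with `labels` (integer array,
#'   0 = background, 1 = GM, 2 = WM, 3 = CSF), `wm_zone` (0 none, 1
#'   single-fiber, 2 crossing), `voxel_size`, `shape`, `preset`, `seed`.
#' @export
phantom_labels <- function(shape = c(32, 32, 32), preset = "default",
                           voxel_size = 1.2, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, voxel_size > 0)
  minsz <- if (preset == "default") 12L else 8L
  if (any(shape < minsz))
    stop("shape ", paste(shape, collapse = "x"),
         " is too small to contain all phantom compartments (need >= ",
         minsz, " per axis for preset '", preset, "')")

  idx <- expand_grid_idx(shape)
  ctr <- (shape + 1) / 2
  ax <- 0.46 * shape
  rho <- sqrt(((idx[, 1] - ctr[1]) / ax[1])^2 +
              ((idx[, 2] - ctr[2]) / ax[2])^2 +
              ((idx[, 3] - ctr[3]) / ax[3])^2)
  lab <- integer(prod(shape))
  zone <- integer(prod(shape))
  inmask <- rho <= 1

  if (preset == "uniform_gm") {
    lab[inmask] <- LABEL_LEVELS[["GM"]]
  } else if (preset == "uniform_wm") {
    lab[inmask] <- LABEL_LEVELS[["WM"]]
    zone[inmask] <- 1L
  } else if (preset == "default") {
    lab[inmask] <- LABEL_LEVELS[["GM"]]
    lab[inmask & rho > 0.86] <- LABEL_LEVELS[["CSF"]]
    slab_hw <- max(1.2, 0.10 * shape[3])
    wm <- inmask & rho <= 0.62 & abs(idx[, 3] - ctr[3]) <= slab_hw
    lab[wm] <- LABEL_LEVELS[["WM"]]
    zone[wm] <- 1L
    cross <- wm & abs(idx[, 1] - ctr[1]) <= 0.15 * shape[1] &
                  abs(idx[, 2] - ctr[2]) <= 0.15 * shape[2]
    zone[cross] <- 2L
  } else stop("unknown phantom preset: ", preset)

  structure(list(labels = array(lab, shape),
                 wm_zone = array(zone, shape),
                 voxel_size = voxel_size, shape = shape,
                 preset = preset, seed = as.integer(seed)),
            class = "ced_labels")
}

# n x 3 integer voxel coordinates for a grid, fastest axis first
expand_grid_idx <- function(shape) {
  cbind(rep(seq_len(shape[1]), times = shape[2] * shape[3]),
        rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
        rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}

#' Default tissue mixture recipes for the phantom
#'
#' Per-tissue Gaussian-mixture displacement recipes, diffusivities in mm2/s.
#' Gray matter is a mildly non-Gaussian isotropic two-compartment mixture;
#' single-fiber white matter mixes a hindered axially-symmetric compartment
#' with a strongly restricted one sharing the same axis, which concentrates
#' non-Gaussianity (and the covariance/DT contrast) in white matter;
#' crossing white matter holds two identical fiber populations at 90
#' degrees; CSF is a single fast isotropic Gaussian.
#'
#' @param jitter relative amplitude of the seeded per-voxel perturbation of
#'   weights and diffusivities (default 0.02).
#' @return nested list of recipes, editable and passed to
#'   [phantom_propagators()].
#' @export
tissue_defaults <- function(jitter = 0.02) {
  list(
    GM = list(d = list(1.0e-3 * diag(3), 0.45e-3 * diag(3)),
              w = c(0.85, 0.15)),
    WM = list( # axial/radial diffusivities, aligned with the local tangent
      hindered   = c(ax = 1.8e-3, rad = 0.35e-3),
      restricted = c(ax = 0.30e-3, rad = 0.05e-3),
      w = c(0.6, 0.4),
      bend_deg = 50),  # total in-plane rotation of the tract tangent
    WM_cross = list(ax = 1.5e-3, rad = 0.30e-3, w = c(0.5, 0.5)),
    CSF = list(d = 2.0e-3),
    jitter = jitter
  )
}

axisym_tensor6 <- function(axis, ax, rad) {
  axis <- axis / sqrt(sum(axis^2))
  m <- rad * diag(3) + (ax - rad) * tcrossprod(axis)
  mat_to_sym6(m)
}

#' Generate Gaussian-mixture propagators for a phantom label map
#'
#' Assigns each in-mask voxel a zero-mean Gaussian-mixture displacement
#' distribution according to its tissue label: the per-voxel propagator
#' P(r | r', Delta) is sum_i w_i N(0, 2 Delta D_i). The white-matter fiber
#' tangent rotates smoothly in the axial plane along the tract; the seed
#' controls small per-voxel perturbations of weights and diffusivity scale.
#'
#' @param labels a `ced_labels` object.
#' @param tissue_params recipes as returned by [tissue_defaults()].
#' @param delta diffusion time Delta, s (default 0.03).
#' @param seed integer seed; defaults to the seed stored in `labels`.
#' @return object of class `ced_propagators`: list with `shape`, `mask_idx`
#'   (linear indices of in-mask voxels), `ncomp`, `weights` (n x kmax),
#'   `tensors` (n x kmax x 6, mm2/s), `delta`, `label` (per-voxel tissue
#'   code), `voxel_size`.
#' @export
phantom_propagators <- function(labels, tissue_params = tissue_defaults(),
                                delta = 0.03, seed = labels$seed) {
  stopifnot(inherits(labels, "ced_labels"), delta > 0)
  shape <- labels$shape
  mask_idx <- which(labels$labels > 0)
  n <- length(mask_idx)
  lab <- labels$labels[mask_idx]
  zone <- labels$wm_zone[mask_idx]
  if (any(!lab %in% LABEL_LEVELS)) stop("unknown tissue label in mask")
  coords <- arrayInd(mask_idx, shape)
  ctr <- (shape + 1) / 2

  kmax <- 2L
  w <- matrix(0, n, kmax)
  tens <- array(0, c(n, kmax, 6))
  ncomp <- integer(n)
  tp <- tissue_params

  with_local_seed(seed, {
    # per-voxel perturbations (smooth recipes + small voxelwise jitter)
    jw <- runif(n, -tp$jitter, tp$jitter)
    jd <- 1 + runif(n, -tp$jitter, tp$jitter)

    for (i in seq_len(n)) {
      if (lab[i] == LABEL_LEVELS[["CSF"]]) {
        ncomp[i] <- 1L
        w[i, 1] <- 1
        tens[i, 1, ] <- mat_to_sym6(tp$CSF$d * jd[i] * diag(3))
      } else if (lab[i] == LABEL_LEVELS[["GM"]]) {
        ncomp[i] <- 2L
        wi <- pmin(pmax(tp$GM$w + c(jw[i], -jw[i]), 0.05), 0.95)
        w[i, ] <- wi / sum(wi)
        tens[i, 1, ] <- mat_to_sym6(tp$GM$d[[1]] * jd[i])
        tens[i, 2, ] <- mat_to_sym6(tp$GM$d[[2]] * jd[i])
      } else if (zone[i] == 2L) { # crossing white matter
        ncomp[i] <- 2L
        wi <- pmin(pmax(tp$WM_cross$w + c(jw[i], -jw[i]), 0.05), 0.95)
        w[i, ] <- wi / sum(wi)
        tens[i, 1, ] <- axisym_tensor6(c(1, 0, 0),
                                       tp$WM_cross$ax * jd[i],
                                       tp$WM_cross$rad * jd[i])
        tens[i, 2, ] <- axisym_tensor6(c(0, 1, 0),
                                       tp$WM_cross$ax * jd[i],
                                       tp$WM_cross$rad * jd[i])
      } else {                    # single-fiber white matter
        ncomp[i] <- 2L
        alpha <- (tp$WM$bend_deg * pi / 180) *
          (coords[i, 1] - ctr[1]) / shape[1]
        tangent <- c(cos(alpha), sin(alpha), 0)
        wi <- pmin(pmax(tp$WM$w + c(jw[i], -jw[i]), 0.05), 0.95)
        w[i, ] <- wi / sum(wi)
        tens[i, 1, ] <- axisym_tensor6(tangent, tp$WM$hindered[["ax"]] * jd[i],
                                       tp$WM$hindered[["rad"]] * jd[i])
        tens[i, 2, ] <- axisym_tensor6(tangent, tp$WM$restricted[["ax"]] * jd[i],
                                       tp$WM$restricted[["rad"]] * jd[i])
      }
    }
  })

  structure(list(shape = shape, mask_idx = mask_idx, ncomp = ncomp,
                 weights = w, tensors = tens, delta = delta, label = lab,
                 voxel_size = labels$voxel_size),
            class = "ced_propagators")
}

#' Synthesize diffusion-weighted signals from mixture propagators
#'
#' Multi-tensor forward model: for a voxel with mixture weights w_i and
#' component diffusivities D_i, the signal at weighting b along unit
#' direction g is `S = S0 * sum_i w_i exp(-b g' D_i g)`. Optional Rician
#' noise models magnitude MR data.
#'
#' @param prop a `ced_propagators` field.
#' @param scheme a `ced_scheme`.
#' @param noise_sigma Rician noise standard deviation in signal units
#'   (default 0 = noiseless).
#' @param seed integer seed for the noise draws.
#' @param S0 unweighted signal level (scalar or per-voxel vector).
#' @return object of class `ced_signals`: list with `shape`, `mask_idx`,
#'   `signals` (n_voxel x n_volume matrix), `S0`, `scheme`.
#' @export
phantom_signals <- function(prop, scheme, noise_sigma = 0, seed = 1L, S0 = 1) {
  stopifnot(inherits(prop, "ced_propagators"), inherits(scheme, "ced_scheme"),
            noise_sigma >= 0)
  n <- length(prop$mask_idx)
  nvol <- length(scheme$b)
  S0 <- rep_len(S0, n)
  sig <- matrix(0, n, nvol)
  # quadratic-form rows for all volumes: nvol x 6
  Q <- t(apply(scheme$dirs, 1, sym6_quadform_row))
  for (k in seq_len(max(prop$ncomp))) {
    active <- prop$ncomp >= k
    if (!any(active)) next
    # adc: n_active x nvol, g' D_k g per volume
    adc <- prop$tensors[active, k, , drop = FALSE]
    dim(adc) <- c(sum(active), 6)
    att <- exp(-(adc %*% t(Q)) * rep(scheme$b, each = sum(active)))
    sig[active, ] <- sig[active, ] + prop$weights[active, k] * att
  }
  sig <- sig * S0
  if (noise_sigma > 0) {
    sig <- with_local_seed(seed, {
      e1 <- matrix(rnorm(n * nvol, 0, noise_sigma), n, nvol)
      e2 <- matrix(rnorm(n * nvol, 0, noise_sigma), n, nvol)
      sqrt((sig + e1)^2 + e2^2)
    })
  }
  structure(list(shape = prop$shape, mask_idx = prop$mask_idx,
                 signals = sig, S0 = S0, scheme = scheme,
                 voxel_size = prop$voxel_size),
            class = "ced_signals")
}

#' Exact second moments of a mixture propagator field
#'
#' For zero-mean Gaussian mixtures the displacement covariance divided by
#' 2*Delta is exactly the weighted component-diffusivity sum
#' `sum_i w_i D_i`; this is the ground-truth propagator covariance tensor
#' (reported, like the diffusion tensor, in mm2/s).
#'
#' @param prop a `ced_propagators` field.
#' @return n x 6 tensor field (mm2/s) with attributes `shape`, `mask_idx`.
#' @export
propagator_moments <- function(prop) {
  stopifnot(inherits(prop, "ced_propagators"))
  n <- length(prop$mask_idx)
  out <- matrix(0, n, 6, dimnames = list(NULL, SYM6_NAMES))
  for (k in seq_len(max(prop$ncomp))) {
    active <- prop$ncomp >= k
    if (!any(active)) next
    tk <- prop$tensors[active, k, , drop = FALSE]
    dim(tk) <- c(sum(active), 6)
    out[active, ] <- out[active, ] + prop$weights[active, k] * tk
  }
  attr(out, "shape") <- prop$shape
  attr(out, "mask_idx") <- prop$mask_idx
  out
}
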