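# Estimation of the water diffusion tensor and of the displacement
# propagator covariance tensor from diffusion-weighted signals, plus the
# scalar maps used to compare them (FA, MD, trace ratio, and the
# difference-in-covariances non-Gaussianity measure).

#' Fit the diffusion tensor from multi-shell signals
#'
#' Linear least-squares fit of the monoexponential model
#' `S = S0 exp(-b g' D g)` on the log-signal, jointly over all weighted
#' volumes (both shells) plus the b = 0 volumes. Voxels with any
#' non-positive signal are flagged and excluded.
#'
#' @param signals a `ced_signals` object.
#' @param scheme acquisition scheme; defaults to the one stored in `signals`.
#' @param weighted if `TRUE`, weight the log-linear fit by squared signal
#'   (the usual WLS correction for log-transformed Rician/Gaussian noise);
#'   the default unweighted fit is exact for noiseless data.
#' @return list of class `ced_dtfit`: `tensor` (n x 6, mm2/s), `S0` (fitted),
#'   `valid` (logical; `FALSE` where the fit was impossible), `shape`,
#'   `mask_idx`.
#' @export
fit_diffusion_tensor <- function(signals, scheme = signals$scheme,
                                 weighted = FALSE) {
  stopifnot(inherits(signals, "ced_signals"))
  b <- scheme$b
  dirs <- scheme$dirs
  wtd <- b > 0
  if (sum(wtd) < 6) stop("need at least 6 diffusion-weighted volumes")
  if (qr(t(apply(dirs[wtd, , drop = FALSE], 1, sym6_quadform_row)))$rank < 6)
    stop("weighted gradient directions are collinear; tensor not identifiable")

  S <- signals$signals
  n <- nrow(S)
  valid <- rowSums(S <= 0) == 0
  X <- cbind(1, -b * t(apply(dirs, 1, sym6_quadform_row)))
  tensor <- matrix(NA_real_, n, 6, dimnames = list(NULL, SYM6_NAMES))
  S0fit <- rep(NA_real_, n)
  if (any(valid)) {
    Y <- t(log(S[valid, , drop = FALSE]))       # nvol x nv
    if (weighted) {
      # per-voxel WLS; loop kept simple, weights = S^2
      vi <- which(valid)
      for (j in seq_along(vi)) {
        wts <- S[vi[j], ]^2
        fit <- stats::lm.wfit(X, Y[, j], wts)
        tensor[vi[j], ] <- fit$coefficients[-1]
        S0fit[vi[j]] <- exp(fit$coefficients[1])
      }
    } else {
      beta <- solve(crossprod(X), crossprod(X, Y))  # 7 x nv
      tensor[valid, ] <- t(beta[-1, , drop = FALSE])
      S0fit[valid] <- exp(beta[1, ])
    }
  }
  structure(list(tensor = tensor, S0 = S0fit, valid = valid,
                 shape = signals$shape, mask_idx = signals$mask_idx),
            class = "ced_dtfit")
}

#' Estimate the propagator covariance tensor
#'
#' The covariance tensor is half the displacement covariance of the
#' diffusion propagator divided by the diffusion time Delta, so it carries
#' mm2/s and reduces exactly to the diffusion tensor when diffusion is
#' Gaussian.
#'
#' Two estimators are provided:
#' * `mode = "ground_truth"` (input is a `ced_propagators` field): the
#'   closed-form mixture covariance `sum_i w_i D_i`.
#' * `mode = "cumulant"` (input is a `ced_signals` object): per direction g
#'   the quadratic cumulant model `log S = log S0 - b a_g + b^2 c_g` is
#'   determined exactly by the b = 0 volumes and the two shells; the b -> 0
#'   apparent diffusivity `a_g` is the directional second moment / 2 Delta,
#'   and a symmetric tensor is least-squares fitted to the set of `a_g`.
#'   Residual error is the O(b^3) cumulant truncation.
#'
#' @param input `ced_propagators` or `ced_signals`, per `mode`.
#' @param scheme acquisition scheme (cumulant mode only; defaults to the one
#'   stored in the signals).
#' @param mode `"ground_truth"` or `"cumulant"`.
#' @return list of class `ced_rfit`: `tensor` (n x 6, mm2/s), `valid`,
#'   `n_clamped` (directional diffusivities clamped at zero), `shape`,
#'   `mask_idx`.
#' @export
estimate_covariance_tensor <- function(input, scheme = NULL,
                                       mode = c("ground_truth", "cumulant")) {
  mode <- match.arg(mode)
  if (mode == "ground_truth") {
    stopifnot(inherits(input, "ced_propagators"))
    tensor <- propagator_moments(input)
    return(structure(list(tensor = tensor[, , drop = FALSE],
                          valid = rep(TRUE, nrow(tensor)), n_clamped = 0L,
                          shape = input$shape, mask_idx = input$mask_idx),
                     class = "ced_rfit"))
  }
  stopifnot(inherits(input, "ced_signals"))
  if (is.null(scheme)) scheme <- input$scheme
  b <- scheme$b
  if (length(unique(b[b > 0])) != 2)
    stop("cumulant mode requires exactly two non-zero b-shells")
  bs <- sort(unique(b[b > 0]))
  b1 <- bs[1]; b2 <- bs[2]

  # pair directions across shells
  d1 <- scheme$dirs[b == b1, , drop = FALSE]
  d2 <- scheme$dirs[b == b2, , drop = FALSE]
  if (nrow(d1) != nrow(d2) || max(abs(d1 - d2)) > 1e-8)
    stop("cumulant mode requires the same gradient directions on both shells")
  if (nrow(d1) < 6) stop("need at least 6 gradient directions")
  Q <- t(apply(d1, 1, sym6_quadform_row))
  if (qr(Q)$rank < 6) stop("gradient directions are collinear")

  S <- input$signals
  n <- nrow(S)
  valid <- rowSums(S <= 0) == 0
  S0 <- rowMeans(S[, b == 0, drop = FALSE])
  Y1 <- -log(S[, b == b1, drop = FALSE] / S0)   # n x ndir
  Y2 <- -log(S[, b == b2, drop = FALSE] / S0)
  # exact quadratic through (0,0),(b1,y1),(b2,y2): a_g = slope at b -> 0
  A <- (Y1 * b2^2 - Y2 * b1^2) / (b1 * b2 * (b2 - b1))
  n_clamped <- sum(A[valid, ] < 0)
  A[A < 0] <- 0
  # least-squares symmetric tensor through the directional diffusivities
  tensor <- matrix(NA_real_, n, 6, dimnames = list(NULL, SYM6_NAMES))
  proj <- solve(crossprod(Q), t(Q))             # 6 x ndir
  tensor[valid, ] <- A[valid, , drop = FALSE] %*% t(proj)
  structure(list(tensor = tensor, valid = valid, n_clamped = n_clamped,
                 shape = input$shape, mask_idx = input$mask_idx),
            class = "ced_rfit")
}

tensor_of <- function(x) {
  if (inherits(x, c("ced_dtfit", "ced_rfit"))) x$tensor else as_sym6_matrix(x)
}

#' Fractional anisotropy of a tensor field
#'
#' Standard eigenvalue-based FA; the zero tensor is assigned FA = 0.
#'
#' @param tf tensor field (n x 6 matrix, fit object, or single tensor).
#' @return numeric vector of FA values in [0, 1].
#' @export
tensor_fa <- function(tf) {
  tf <- tensor_of(tf)
  ev <- field_eigen(tf)$values
  md <- rowMeans(ev)
  num <- rowSums((ev - md)^2)
  den <- rowSums(ev^2)
  fa <- sqrt(1.5 * num / den)
  fa[den <= 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Mean diffusivity of a tensor field
#'
#' @param tf tensor field (n x 6 matrix, fit object, or single tensor).
#' @return numeric vector, trace/3 per voxel (mm2/s for diffusivities).
#' @export
tensor_md <- function(tf) {
  sym6_trace(tensor_of(tf)) / 3
}

#' Voxelwise ratio of tensor traces
#'
#' `Tr(R)/Tr(D)` compares the overall displacement range implied by the
#' propagator covariance with that of the fitted diffusion tensor; the
#' ratio is exactly 1 in the Gaussian limit.
#'
#' @param R,D tensor fields on the same voxel set.
#' @param eps voxels with `Tr(D) < eps` are masked out (`NA`).
#' @return numeric vector of ratios; attribute `"n_masked"` counts the
#'   voxels excluded by the trace floor.
#' @export
trace_ratio <- function(R, D, eps = 1e-12) {
  R <- tensor_of(R); D <- tensor_of(D)
  stopifnot(nrow(R) == nrow(D))
  trR <- sym6_trace(R); trD <- sym6_trace(D)
  out <- trR / trD
  bad <- !is.na(trD) & trD < eps
  out[bad] <- NA_real_
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Difference in covariances (DC): second-order diffusion non-Gaussianity
#'
#' DC measures, per voxel, how far the displacement distribution implied by
#' the propagator covariance is from the Gaussian the diffusion tensor fit
#' assumes. It is computed as the squared Bures-Wasserstein distance
#' between the two zero-mean Gaussians with covariances `2 Delta R` and
#' `2 Delta D`:
#' `DC = Tr(S_R) + Tr(S_D) - 2 Tr[(S_D^{1/2} S_R S_D^{1/2})^{1/2}]`,
#' the minimal expected squared displacement discrepancy over all couplings
#' of the two distributions. DC is non-negative, carries mm2, and is zero
#' exactly when the two covariances coincide (Gaussian diffusion at second
#' order).
#'
#' @param R,D tensor fields in mm2/s on the same voxel set.
#' @param delta diffusion time Delta, s.
#' @return numeric vector of DC values (mm2).
#' @export
covariance_difference <- function(R, D, delta = 0.03) {
  stopifnot(delta > 0)
  R <- tensor_of(R); D <- tensor_of(D)
  stopifnot(nrow(R) == nrow(D))
  R <- spd_repair(R); D <- spd_repair(D)
  if (attr(R, "repaired") + attr(D, "repaired") > 0)
    warning("non-SPD tensors repaired before DC computation")
  n <- nrow(R)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(R[i, ]) || anyNA(D[i, ])) next
    Sr <- 2 * delta * sym6_to_mat(R[i, ])
    Sd <- 2 * delta * sym6_to_mat(D[i, ])
    sd_half <- mat_sqrt_spd(Sd)
    cross <- mat_sqrt_spd(sd_half %*% Sr %*% sd_half)
    out[i] <- max(0, sum(diag(Sr)) + sum(diag(Sd)) - 2 * sum(diag(cross)))
  }
  out
}
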