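# Independent oracles and fixture builders used across the test files.

# small two-shell scheme for cheap unit tests (full 61-dir scheme is used
# where the protocol matters)
small_scheme <- function(n_dirs = 21, delta = 0.03)
  two_shell_scheme(n_dirs = n_dirs, delta = delta)

# hand-build a mixture propagator field on an arbitrary voxel set
make_propagators <- function(tensors, weights, shape = c(1, 1, 1),
                             mask_idx = 1L, delta = 0.03, label = 1L,
                             voxel_size = 1.2) {
  # tensors: list over voxels of (k x 6) matrices; weights: list of k-vectors
  n <- length(mask_idx)
  kmax <- max(vapply(weights, length, 1L))
  W <- matrix(0, n, kmax)
  TT <- array(0, c(n, kmax, 6))
  nc <- integer(n)
  for (i in seq_len(n)) {
    k <- length(weights[[i]])
    nc[i] <- k
    W[i, seq_len(k)] <- weights[[i]]
    TT[i, seq_len(k), ] <- tensors[[i]]
  }
  structure(list(shape = shape, mask_idx = mask_idx, ncomp = nc,
                 weights = W, tensors = TT, delta = delta,
                 label = rep_len(label, n), voxel_size = voxel_size),
            class = "ced_propagators")
}

single_gaussian_prop <- function(d6 = c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3),
                                 delta = 0.03) {
  make_propagators(list(matrix(d6, 1, 6)), list(1), delta = delta)
}

# Monte-Carlo displacement covariance of a Gaussian mixture (independent
# sampling oracle for the closed-form second moments)
mc_mixture_covariance <- function(weights, tensors6, delta, n_samp = 1e6) {
  k <- sample.int(length(weights), n_samp, replace = TRUE, prob = weights)
  x <- matrix(0, n_samp, 3)
  for (j in seq_along(weights)) {
    idx <- which(k == j)
    if (!length(idx)) next
    L <- chol(2 * delta * sym6_to_mat(tensors6[j, ]))
    x[idx, ] <- matrix(rnorm(3 * length(idx)), ncol = 3) %*% L
  }
  crossprod(x) / n_samp  # zero-mean displacement covariance
}

# Brute-force optimal-transport oracle for the squared Bures-Wasserstein
# distance between zero-mean Gaussians: among linear maps pushing
# N(0, Sd) to N(0, Sr) (A = Sr^{1/2} U Sd^{-1/2}, U orthogonal) the
# expected squared displacement Tr(Sr) + Tr(Sd) - 2 Tr(Sr^{1/2} U Sd^{1/2})
# is minimized numerically over the orthogonal group (Euler angles, both
# determinant signs, multi-start). Independent of the matrix-square-root
# identity used by the implementation.
bures_sq_oracle <- function(Sr, Sd, n_starts = 12) {
  sqr <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3) %*% t(e$vectors)
  }
  Ar <- sqr(Sr); Ad <- sqr(Sd)
  rot <- function(th) {
    cz <- cos(th[1]); sz <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  best <- -Inf
  for (refl in list(diag(3), diag(c(1, 1, -1)))) {
    for (s in seq_len(n_starts)) {
      th0 <- runif(3, -pi, pi)
      opt <- optim(th0, function(th)
        -sum(diag(Ar %*% rot(th) %*% refl %*% Ad)),
        method = "Nelder-Mead",
        control = list(maxit = 600, reltol = 1e-13))
      best <- max(best, -opt$value)
    }
  }
  max(0, sum(diag(Sr)) + sum(diag(Sd)) - 2 * best)
}

# reference floating-point line rasterizer: walks the driving axis and
# rounds the other coordinates; steps whose ideal coordinate is an exact
# half-integer tie are reported so callers can exclude them
raster_line <- function(a, b) {
  d <- b - a
  ad <- abs(d)
  n <- max(ad)
  if (n == 0) return(list(line = matrix(a, 1, 3), tie = FALSE))
  drv <- which.max(ad)
  out <- matrix(0L, n + 1, 3)
  tie <- logical(n + 1)
  for (k in 0:n) {
    t <- k / ad[drv]
    ideal <- a + t * d
    # exact tie when 2*k*|d_o| is an odd multiple of |d_drv|
    for (o in setdiff(1:3, drv)) {
      num <- 2L * k * abs(d[o])
      if (ad[drv] > 0 && num %% (2L * ad[drv]) == ad[drv]) tie[k + 1] <- TRUE
    }
    out[k + 1, ] <- floor(ideal + 0.5)
    out[k + 1, drv] <- a[drv] + k * sign(d[drv])
  }
  list(line = out, tie = tie)
}

# zero-velocity flow object for diffusion-only transport tests
zero_flow <- function(mesh) {
  structure(list(p = numeric(mesh$n_cells),
                 face_flux = numeric(nrow(mesh$int_faces)),
                 bnd_flux = numeric(nrow(mesh$bnd_faces)),
                 v_cell = matrix(0, mesh$n_cells, 3), Q = 0, dp = 0,
                 iterations = 0L, div_residual = 0),
            class = "ced_flow")
}

# isotropic constant tensor field over a mesh
iso_field <- function(n, value) {
  matrix(rep(c(value, 0, 0, value, 0, value), each = n), n, 6)
}

# dense independent reconstruction of the implicit transport operator
# (upwind advection + face-normal tensor diffusion + boundary outflow),
# used for the concentration-difference identity check
dense_transport_operator <- function(mesh, flow, tensor, phi) {
  n <- mesh$n_cells
  A <- mesh$face_area; h <- mesh$h
  nn_col <- c(1, 4, 6)
  phik <- tensor * phi
  M <- matrix(0, n, n)
  f <- mesh$int_faces
  for (r in seq_len(nrow(f))) {
    i <- f[r, 1]; j <- f[r, 2]; a <- f[r, 3]
    Fv <- flow$face_flux[r]
    gD <- A / h * 0.5 * (phik[i, nn_col[a]] + phik[j, nn_col[a]])
    M[i, i] <- M[i, i] + max(Fv, 0) + gD
    M[i, j] <- M[i, j] - max(-Fv, 0) - gD
    M[j, j] <- M[j, j] + max(-Fv, 0) + gD
    M[j, i] <- M[j, i] - max(Fv, 0) - gD
  }
  bc <- mesh$bnd_faces
  for (r in seq_len(nrow(bc))) {
    cc <- bc[r, 1]
    M[cc, cc] <- M[cc, cc] + max(flow$bnd_flux[r], 0)
  }
  M
}
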