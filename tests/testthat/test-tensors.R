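# Tensor estimation (DT fit, covariance tensor) and scalar comparison maps.

test_that("DT fit is exact for a noiseless single Gaussian and flags bad voxels", {
  sch <- two_shell_scheme()
  d6 <- c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3)
  prop <- single_gaussian_prop(d6)
  sig <- phantom_signals(prop, sch)
  fit <- fit_diffusion_tensor(sig)
  expect_lt(max(abs(fit$tensor[1, ] - d6)), 1e-9)
  expect_equal(fit$S0[1], 1, tolerance = 1e-12)
  expect_equal(tensor_fa(matrix(c(1e-3, 0, 0, 1e-3, 0, 1e-3), 1, 6)), 0)

  # a voxel with non-positive signal is excluded
  sig$signals[1, 5] <- 0
  fit2 <- fit_diffusion_tensor(sig)
  expect_false(fit2$valid[1])
  expect_true(all(is.na(fit2$tensor[1, ])))

  # insufficient directions fail loudly
  bad <- structure(list(b = c(0, 1000, 1000), dirs = rbind(0, c(1, 0, 0), c(0, 1, 0)),
                        n_b0 = 1, delta = 0.03), class = "ced_scheme")
  expect_error(fit_diffusion_tensor(sig, scheme = bad), "at least 6")
})

test_that("kurtosis biases the monoexponential fit low in mixture voxels", {
  sch <- two_shell_scheme()
  pw <- make_propagators(
    list(rbind(c(1.8e-3, 0, 0, 0.35e-3, 0, 0.35e-3),
               c(0.3e-3, 0, 0, 0.05e-3, 0, 0.05e-3))),
    list(c(0.6, 0.4)))
  sig <- phantom_signals(pw, sch)
  fit <- fit_diffusion_tensor(sig)
  tr_fit <- sum(fit$tensor[1, c(1, 4, 6)])
  tr_true <- sum(propagator_moments(pw)[1, c(1, 4, 6)])
  expect_lt(tr_fit, tr_true)
})

test_that("covariance-tensor estimators agree with the Gaussian and mixture ground truth", {
  sch <- two_shell_scheme()
  d6 <- c(1.2e-3, 1e-4, 0, 0.6e-3, -5e-5, 0.5e-3)
  prop <- single_gaussian_prop(d6)
  # Gaussian voxel: both modes return D exactly (quadratic term vanishes)
  gt <- estimate_covariance_tensor(prop, mode = "ground_truth")
  expect_equal(gt$tensor[1, ], setNames(d6, colnames(gt$tensor)), tolerance = 1e-15)
  cm <- estimate_covariance_tensor(phantom_signals(prop, sch), mode = "cumulant")
  expect_lt(max(abs(cm$tensor[1, ] - d6)), 1e-12)

  # equal-weight mixture of diag(2,1,1), diag(1,2,1) (x 1e-3)
  mix <- make_propagators(
    list(rbind(c(2e-3, 0, 0, 1e-3, 0, 1e-3), c(1e-3, 0, 0, 2e-3, 0, 1e-3))),
    list(c(0.5, 0.5)))
  gtm <- estimate_covariance_tensor(mix, mode = "ground_truth")
  expect_equal(unname(gtm$tensor[1, ]), c(1.5e-3, 0, 0, 1.5e-3, 0, 1e-3))
  cmm <- estimate_covariance_tensor(phantom_signals(mix, sch), mode = "cumulant")
  # cumulant truncation error stays below 5% of the ground-truth scale
  expect_lt(max(abs(cmm$tensor[1, ] - gtm$tensor[1, ])),
            0.05 * max(abs(gtm$tensor[1, ])))

  # one-shell schemes cannot determine the quadratic
  one <- two_shell_scheme(n_dirs = 21, bvals = 1200)
  expect_error(estimate_covariance_tensor(phantom_signals(mix, one),
                                          mode = "cumulant"), "two non-zero")
})

test_that("FA and MD follow the eigenvalue definitions", {
  expect_equal(tensor_fa(diag(3)), 0)
  expect_equal(tensor_md(diag(3)), 1)
  expect_equal(tensor_fa(matrix(c(1, 0, 0, 0, 0, 0), 1, 6)), 1)
  # closed trace form cross-check: FA^2 = 3/2 (Tr(T^2) - 3 MD^2)/Tr(T^2)
  set.seed(7)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    M <- crossprod(A) + diag(3) * 0.1
    t6 <- mat_to_sym6(M)
    md <- sum(diag(M)) / 3
    tr2 <- sum(M * M)
    fa_ref <- sqrt(1.5 * (tr2 - 3 * md^2) / tr2)
    expect_equal(tensor_fa(t6), fa_ref, tolerance = 1e-12)
    expect_equal(tensor_md(t6), md, tolerance = 1e-12)
  }
})

test_that("trace ratio is 1 for Gaussian voxels, 2 for doubled tensors, masked at zero", {
  sch <- two_shell_scheme()
  prop <- single_gaussian_prop()
  sig <- phantom_signals(prop, sch)
  dfit <- fit_diffusion_tensor(sig)
  rfit <- estimate_covariance_tensor(sig, mode = "cumulant")
  expect_equal(trace_ratio(rfit, dfit)[1], 1, tolerance = 1e-10)

  D <- matrix(c(1e-3, 0, 0, 2e-3, 0, 3e-3), 1, 6)
  expect_equal(trace_ratio(2 * D, D)[1], 2)
  r <- trace_ratio(D, 0 * D)
  expect_true(is.na(r[1]))
  expect_equal(attr(r, "n_masked"), 1)

  # default WM phantom voxel: restricted compartment depresses the DT fit
  lab <- phantom_labels(c(16, 16, 16), "default", seed = 1)
  prop <- phantom_propagators(lab, seed = 1)
  sig <- phantom_signals(prop, sch)
  tr <- trace_ratio(estimate_covariance_tensor(sig, mode = "cumulant"),
                    fit_diffusion_tensor(sig))
  expect_true(all(tr[prop$label == 2] > 1))
})

test_that("DC is zero iff covariances match and follows the commuting closed form", {
  delta <- 0.03
  D <- matrix(c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3), 1, 6)
  expect_equal(covariance_difference(D, D, delta)[1], 0, tolerance = 1e-15)

  # isotropic quadrupling: DC = Tr(Sigma_D) (per-eigenvalue (sqrt a - sqrt b)^2)
  expect_equal(covariance_difference(4 * D, D, delta)[1],
               2 * delta * sum(D[c(1, 4, 6)]), tolerance = 1e-12)

  # commuting (co-diagonal) pair closed form
  lamR <- c(2.2e-3, 0.9e-3, 0.4e-3); lamD <- c(1.5e-3, 1.0e-3, 0.2e-3)
  dcv <- covariance_difference(matrix(c(lamR[1], 0, 0, lamR[2], 0, lamR[3]), 1, 6),
                               matrix(c(lamD[1], 0, 0, lamD[2], 0, lamD[3]), 1, 6),
                               delta)
  closed <- sum((sqrt(2 * delta * lamR) - sqrt(2 * delta * lamD))^2)
  expect_equal(dcv[1], closed, tolerance = 1e-12)

  # DC strictly positive when covariances differ
  expect_gt(dcv[1], 0)
})

test_that("DC equals the optimal-coupling displacement cost (transport oracle)", {
  set.seed(11)
  delta <- 0.03
  for (i in 1:4) {
    A <- matrix(rnorm(9), 3, 3); B <- matrix(rnorm(9), 3, 3)
    R6 <- mat_to_sym6(crossprod(A) * 1e-4 + 1e-4 * diag(3))
    D6 <- mat_to_sym6(crossprod(B) * 1e-4 + 1e-4 * diag(3))
    dc <- covariance_difference(matrix(R6, 1, 6), matrix(D6, 1, 6), delta)[1]
    oracle <- bures_sq_oracle(2 * delta * sym6_to_mat(R6),
                              2 * delta * sym6_to_mat(D6))
    expect_equal(dc, oracle, tolerance = 1e-5)
  }
})

test_that("FA, MD and DC are invariant under a common rotation", {
  set.seed(3)
  sch <- two_shell_scheme()
  # random rotation via QR
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  d6 <- c(1.5e-3, 2e-4, -1e-4, 0.7e-3, 5e-5, 0.4e-3)
  r6 <- c(1.8e-3, 1e-4, 0, 0.9e-3, -5e-5, 0.6e-3)
  d6r <- cedsim:::rotate_sym6(matrix(d6, 1, 6), Q)
  r6r <- cedsim:::rotate_sym6(matrix(r6, 1, 6), Q)
  expect_equal(tensor_fa(d6r), tensor_fa(matrix(d6, 1, 6)), tolerance = 1e-8)
  expect_equal(tensor_md(d6r), tensor_md(matrix(d6, 1, 6)), tolerance = 1e-12)
  expect_equal(covariance_difference(r6r, d6r)[1],
               covariance_difference(matrix(r6, 1, 6), matrix(d6, 1, 6))[1],
               tolerance = 1e-8)

  # rotating gradients and the underlying tensor together leaves the DT
  # fit equivariant: fitted tensor rotates accordingly
  prop_rot <- single_gaussian_prop(as.numeric(d6r))
  sch_fit <- fit_diffusion_tensor(phantom_signals(prop_rot, sch))
  expect_lt(max(abs(sch_fit$tensor[1, ] - d6r)), 1e-9)
})

test_that("Gaussian-limit collapse: all-Gaussian phantom gives R = D, DC = 0, ratio = 1", {
  # CSF-like single-Gaussian voxels everywhere
  lab <- phantom_labels(c(12, 12, 12), "uniform_gm", seed = 1)
  prop <- phantom_propagators(lab, seed = 1)
  # replace GM mixtures by their Gaussian mean so every voxel is Gaussian
  mom <- propagator_moments(prop)
  gauss <- make_propagators(
    lapply(seq_len(nrow(mom)), function(i) matrix(mom[i, ], 1, 6)),
    rep(list(1), nrow(mom)), shape = prop$shape, mask_idx = prop$mask_idx)
  sig <- phantom_signals(gauss, two_shell_scheme())
  dfit <- fit_diffusion_tensor(sig)
  rfit <- estimate_covariance_tensor(sig, mode = "cumulant")
  expect_lt(max(abs(rfit$tensor - dfit$tensor)), 1e-9)
  expect_lt(max(covariance_difference(rfit, dfit)), 1e-10)
  expect_equal(max(abs(trace_ratio(rfit, dfit) - 1)), 0, tolerance = 1e-8)
})

test_that("covariance FA exceeds DT FA in nearly all white-matter voxels", {
  lab <- phantom_labels(c(20, 20, 20), "default", seed = 4)
  prop <- phantom_propagators(lab, seed = 4)
  sig <- phantom_signals(prop, two_shell_scheme())
  faR <- tensor_fa(estimate_covariance_tensor(sig, mode = "cumulant"))
  faD <- tensor_fa(fit_diffusion_tensor(sig))
  wm <- prop$label == 2
  expect_gte(mean(faR[wm] >= faD[wm]), 0.9)
})
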