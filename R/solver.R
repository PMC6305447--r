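# Weakly coupled CED solver on the voxelized mesh: a steady anisotropic
# Darcy pressure solve (continuity + tensor Darcy law) fixes the velocity
# field, then the transient advection-diffusion transport equation
#   phi dC/dt = -div(v C) + div(phi Tensor grad C)
# is integrated with backward-Euler time stepping, first-order upwind
# advection and full-tensor diffusion. The same machinery serves the
# R-model (effective permeability + covariance tensor) and the D-model
# (hydraulic conductivity + diffusion tensor); only the tensor fields
# supplied differ.

# tangential axes and sym6 cross-component indices for each face normal
CROSS_TANG <- list(`1` = cbind(t = c(2, 3), comp = c(2, 3)),
                   `2` = cbind(t = c(1, 3), comp = c(2, 5)),
                   `3` = cbind(t = c(1, 2), comp = c(3, 5)))

#' Describe the infusion source
#'
#' @param cell index of the source cell in the mesh (the catheter opening
#'   is one voxel, ~1.2 mm, a realistic opening size). A vector of cells
#'   shares the infusion rate equally (used e.g. for the children of a
#'   coarse source cell on a refined mesh, keeping the physical opening).
#' @param rate_ul_min constant infusion rate in ul/min (1 ul/min =
#'   1/60 mm3/s), or `NULL` when `schedule` is given.
#' @param schedule data frame with columns `time` (s, segment start; first
#'   row must be 0) and `rate_ul_min`, for piecewise-constant schedules
#'   such as 2.5 ul/min for 30 min followed by 5 ul/min.
#' @param C_in infusate concentration (dimensionless, default 1).
#' @param p_b Dirichlet boundary pressure, Pa (default 0).
#' @param mode `"rate"` (fixed volumetric inflow; the clinically controlled
#'   quantity, primary mode) or `"pressure"` (fixed source-boundary
#'   pressure difference `dp`; infusion rate emergent).
#' @param dp source-minus-boundary pressure difference for
#'   `mode = "pressure"`, Pa (default 3500).
#' @return list of class `ced_source`.
#' @export
source_spec <- function(cell, rate_ul_min = NULL, schedule = NULL, C_in = 1,
                        p_b = 0, mode = c("rate", "pressure"), dp = 3500) {
  mode <- match.arg(mode)
  if (is.null(schedule)) {
    if (mode == "rate") stopifnot(!is.null(rate_ul_min), rate_ul_min >= 0)
    schedule <- data.frame(time = 0, rate_ul_min = if (is.null(rate_ul_min)) NA_real_ else rate_ul_min)
  } else {
    stopifnot(is.data.frame(schedule), all(c("time", "rate_ul_min") %in% names(schedule)),
              schedule$time[1] == 0, !is.unsorted(schedule$time),
              all(schedule$rate_ul_min >= 0))
  }
  structure(list(cell = as.integer(cell), schedule = schedule, C_in = C_in,
                 p_b = p_b, mode = mode, dp = dp),
            class = "ced_source")
}

# infusion rate (mm3/s) active at time t
source_rate <- function(source, t) {
  i <- findInterval(t, source$schedule$time, rightmost.closed = FALSE)
  source$schedule$rate_ul_min[max(i, 1)] / 60
}

# cell-centred gradient of a per-cell scalar (central where both neighbors
# exist, one-sided at the mask edge, 0 where isolated)
cell_gradient <- function(mesh, x) {
  n <- mesh$n_cells
  g <- matrix(0, n, 3)
  h <- mesh$h
  for (a in 1:3) {
    nm <- mesh$neighbors[, 2 * a - 1]
    np <- mesh$neighbors[, 2 * a]
    both <- nm > 0 & np > 0
    onlym <- nm > 0 & np == 0
    onlyp <- nm == 0 & np > 0
    g[both, a] <- (x[np[both]] - x[nm[both]]) / (2 * h)
    g[onlym, a] <- (x[onlym] - x[nm[onlym]]) / h
    g[onlyp, a] <- (x[np[onlyp]] - x[onlyp]) / h
  }
  g
}

# precomputed sparse operators for the hot loop: face-flux divergence
# (n_cells x n_faces, +1 at i, -1 at j) and per-axis gradient matrices
mesh_operators <- function(mesh) {
  n <- mesh$n_cells
  f <- mesh$int_faces
  nf <- nrow(f)
  Div <- Matrix::sparseMatrix(i = c(f[, "i"], f[, "j"]),
                              j = rep(seq_len(nf), 2),
                              x = c(rep(1, nf), rep(-1, nf)),
                              dims = c(n, nf))
  h <- mesh$h
  G <- vector("list", 3)
  for (a in 1:3) {
    nm <- mesh$neighbors[, 2 * a - 1]
    np <- mesh$neighbors[, 2 * a]
    both <- which(nm > 0 & np > 0)
    onlym <- which(nm > 0 & np == 0)
    onlyp <- which(nm == 0 & np > 0)
    ii <- c(both, both, onlym, onlym, onlyp, onlyp)
    jj <- c(np[both], nm[both], onlym, nm[onlym], np[onlyp], onlyp)
    xx <- c(rep(1 / (2 * h), length(both)), rep(-1 / (2 * h), length(both)),
            rep(1 / h, length(onlym)), rep(-1 / h, length(onlym)),
            rep(1 / h, length(onlyp)), rep(-1 / h, length(onlyp)))
    G[[a]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  }
  list(Div = Div, G = G)
}

# fast cross-term face fluxes using precomputed operators; returns NULL
# when all off-diagonal tensor components vanish
cross_face_flux_ops <- function(mesh, ops, tensor, x) {
  if (all(tensor[, c(2, 3, 5)] == 0)) return(NULL)
  grad <- cbind(as.numeric(ops$G[[1]] %*% x),
                as.numeric(ops$G[[2]] %*% x),
                as.numeric(ops$G[[3]] %*% x))
  cross_face_flux(mesh, tensor, grad)
}

# cross-term (tensor off-diagonal) fluxes across interior faces, oriented
# +axis from i to j: F = -A * sum_t kappa_nt(face) * dx_t(face)
cross_face_flux <- function(mesh, tensor, grad) {
  f <- mesh$int_faces
  A <- mesh$face_area
  out <- numeric(nrow(f))
  for (a in 1:3) {
    rows <- f[, "axis"] == a
    if (!any(rows)) next
    i <- f[rows, "i"]; j <- f[rows, "j"]
    acc <- 0
    ct <- CROSS_TANG[[a]]
    for (k in 1:2) {
      kt <- 0.5 * (tensor[i, ct[k, "comp"]] + tensor[j, ct[k, "comp"]])
      gt <- 0.5 * (grad[i, ct[k, "t"]] + grad[j, ct[k, "t"]])
      acc <- acc + kt * gt
    }
    out[rows] <- -A * acc
  }
  out
}

#' Solve the steady Darcy pressure problem
#'
#' Finite-volume discretization of `div(v) = 0`, `v = -K grad p` with
#' Dirichlet pressure `p_b` on all boundary faces and the infusion source
#' as either a fixed volumetric inflow Q at the source cell (`mode =
#' "rate"`) or a fixed source pressure (`mode = "pressure"`). Face-normal
#' conductances use arithmetically averaged face tensors; tensor
#' cross-derivative terms are handled by deferred correction (evaluated
#' from the previous iterate) so the assembled matrix stays 7-point SPD.
#'
#' @param mesh a `ced_mesh`.
#' @param conductivity SPD tensor field, n x 6 (mm2/(Pa s) scale).
#' @param source a `ced_source`; for schedules the rate at `t` is used.
#' @param t time at which to read the infusion schedule (default 0).
#' @param tol relative deferred-correction convergence tolerance.
#' @param max_iter iteration cap for the deferred correction.
#' @return list of class `ced_flow`: `p` (Pa), `face_flux` (mm3/s per
#'   interior face, oriented +axis), `bnd_flux` (mm3/s outward per boundary
#'   face), `v_cell` (n x 3 Darcy velocity, mm/s), `Q` (source rate used,
#'   mm3/s), `dp` (emergent source-boundary pressure difference),
#'   `iterations`, `div_residual` (max interior divergence, mm3/s).
#' @export
solve_pressure <- function(mesh, conductivity, source, t = 0,
                           tol = 1e-12, max_iter = 400) {
  stopifnot(inherits(mesh, "ced_mesh"), inherits(source, "ced_source"))
  conductivity <- as_sym6_matrix(conductivity)
  stopifnot(nrow(conductivity) == mesh$n_cells)
  if (any(source$cell < 1 | source$cell > mesh$n_cells))
    stop("source cell outside the mesh")
  if (nrow(mesh$bnd_faces) == 0)
    stop("mesh has no boundary faces; Dirichlet condition cannot be applied")
  nn_col <- c(1, 4, 6)
  A <- mesh$face_area; h <- mesh$h
  f <- mesh$int_faces
  knn_i <- conductivity[cbind(f[, "i"], nn_col[f[, "axis"]])]
  knn_j <- conductivity[cbind(f[, "j"], nn_col[f[, "axis"]])]
  if (any(conductivity[, nn_col] <= 0))
    stop("conductivity field is not positive definite")
  g_int <- A / h * 0.5 * (knn_i + knn_j)
  bc <- mesh$bnd_faces
  g_bnd <- A / (h / 2) * conductivity[cbind(bc[, "cell"], nn_col[bc[, "axis"]])]

  n <- mesh$n_cells
  ii <- c(f[, "i"], f[, "j"], f[, "i"], f[, "j"], bc[, "cell"])
  jj <- c(f[, "i"], f[, "j"], f[, "j"], f[, "i"], bc[, "cell"])
  xx <- c(g_int, g_int, -g_int, -g_int, g_bnd)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  b0 <- rowsum_into(g_bnd, bc[, "cell"], n) * source$p_b

  fixed_p <- source$mode == "pressure"
  if (fixed_p) {
    pen <- 1e14 * max(Matrix::diag(M))
    for (sc in source$cell) M[sc, sc] <- M[sc, sc] + pen
  } else {
    Q <- source_rate(source, t)
    b0[source$cell] <- b0[source$cell] + Q / length(source$cell)
  }

  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE, perm = TRUE)
  ops <- mesh_operators(mesh)
  p <- numeric(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    b <- b0
    Fc <- cross_face_flux_ops(mesh, ops, conductivity, p)
    if (!is.null(Fc)) b <- b - as.numeric(ops$Div %*% Fc)
    if (fixed_p) b[source$cell] <- b[source$cell] + pen * (source$p_b + source$dp)

    p_new <- as.numeric(Matrix::solve(ch, b))
    dchg <- max(abs(p_new - p)) / max(max(abs(p_new)), .Machine$double.xmin)
    p <- p_new
    if (is.null(Fc) || dchg < tol || iter >= max_iter) break
  }

  Fc <- cross_face_flux_ops(mesh, ops, conductivity, p)
  if (is.null(Fc)) Fc <- 0
  face_flux <- g_int * (p[f[, "i"]] - p[f[, "j"]]) + Fc
  bnd_flux <- g_bnd * (p[bc[, "cell"]] - source$p_b)

  div <- rowsum_into(face_flux, f[, "i"], n) - rowsum_into(face_flux, f[, "j"], n) +
         rowsum_into(bnd_flux, bc[, "cell"], n)
  Q_eff <- if (fixed_p) sum(bnd_flux) else source_rate(source, t)
  div_res <- max(abs(div[-source$cell]))

  # Darcy (superficial) cell-centre velocity from face fluxes
  v <- matrix(0, n, 3)
  cnt <- matrix(0, n, 3)
  for (a in 1:3) {
    rows <- f[, "axis"] == a
    i <- f[rows, "i"]; j <- f[rows, "j"]; fa <- face_flux[rows] / A
    v[, a] <- rowsum_into(fa, i, n) + rowsum_into(fa, j, n)
    cnt[, a] <- rowsum_into(rep(1, sum(rows)), i, n) + rowsum_into(rep(1, sum(rows)), j, n)
    rows <- bc[, "axis"] == a
    fa <- bc[rows, "side"] * bnd_flux[rows] / A
    v[, a] <- v[, a] + rowsum_into(fa, bc[rows, "cell"], n)
    cnt[, a] <- cnt[, a] + rowsum_into(rep(1, sum(rows)), bc[rows, "cell"], n)
  }
  v <- v / pmax(cnt, 1)

  structure(list(p = p, face_flux = face_flux, bnd_flux = bnd_flux,
                 v_cell = v, Q = Q_eff,
                 dp = mean(p[source$cell]) - source$p_b,
                 iterations = iter, div_residual = div_res),
            class = "ced_flow")
}

# sum values into an n-vector by index (dense rowsum)
rowsum_into <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# Build the implicit transport stepper: backward-Euler, upwind advection,
# full-tensor diffusion (normal terms implicit, cross terms deferred by one
# step). Returns an environment with a step(C) closure.
transport_stepper <- function(mesh, flow, tensor, phi, dt, source, Q,
                              face_avg = c("arithmetic", "harmonic")) {
  face_avg <- match.arg(face_avg)
  n <- mesh$n_cells
  A <- mesh$face_area; h <- mesh$h; V <- mesh$cell_volume
  f <- mesh$int_faces
  nn_col <- c(1, 4, 6)
  phik <- tensor * phi   # phi * tensor, row-scaled
  ki <- phik[cbind(f[, "i"], nn_col[f[, "axis"]])]
  kj <- phik[cbind(f[, "j"], nn_col[f[, "axis"]])]
  gD <- if (face_avg == "arithmetic") A / h * 0.5 * (ki + kj)
        else A / h * ifelse(ki + kj > 0, 2 * ki * kj / (ki + kj), 0)

  Fup <- pmax(flow$face_flux, 0)   # carries C_i (i -> j)
  Fdn <- pmax(-flow$face_flux, 0)  # carries C_j
  bc <- mesh$bnd_faces
  Fout <- pmax(flow$bnd_flux, 0)   # advective outflow; inflow carries C = 0

  ii <- c(f[, "i"], f[, "j"], f[, "i"], f[, "j"],
          f[, "i"], f[, "j"], f[, "i"], f[, "j"], bc[, "cell"])
  jj <- c(f[, "i"], f[, "j"], f[, "j"], f[, "i"],
          f[, "i"], f[, "j"], f[, "j"], f[, "i"], bc[, "cell"])
  xx <- c(Fup, Fdn, -Fdn, -Fup,
          gD, gD, -gD, -gD, Fout)
  Aop <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Pdt <- phi * V / dt
  M <- as(Aop + Matrix::Diagonal(n, Pdt), "CsparseMatrix")
  # pure-diffusion systems are symmetric: use sparse Cholesky; otherwise a
  # diagonal-pivot LU with AMD ordering (M is an M-matrix with positive
  # diagonal, so pivoting down the diagonal is stable)
  LU <- if (all(flow$face_flux == 0) && all(Fout == 0))
    Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE, perm = TRUE)
  else Matrix::lu(M, order = 1L, tol = 0)
  ops <- mesh_operators(mesh)
  bcell <- bc[, "cell"]
  has_cross <- !all(phik[, c(2, 3, 5)] == 0)

  env <- new.env(parent = emptyenv())
  env$dt <- dt
  env$step <- function(C) {
    rhs <- Pdt * C
    if (has_cross) {
      Fc <- cross_face_flux_ops(mesh, ops, phik, C)
      rhs <- rhs - as.numeric(ops$Div %*% Fc)
    }
    rhs[source$cell] <- rhs[source$cell] + Q * source$C_in / length(source$cell)
    C_new <- as.numeric(Matrix::solve(LU, rhs))
    out <- sum(Fout * C_new[bcell]) * dt
    list(C = C_new, outflux = out, injected = Q * source$C_in * dt)
  }
  env
}

#' Advance the drug concentration field
#'
#' Takes `n_steps` implicit (backward-Euler) steps of the finite-volume
#' transport equation at fixed velocity (weak coupling): first-order upwind
#' advective fluxes from the stored face fluxes, implicit face-normal
#' tensor diffusion on `phi * tensor`, explicit (previous-step) tensor
#' cross terms, source mass `Q * C_in` into the source cell, advective
#' outflow and zero diffusive flux at boundary faces. The mass ledger
#' (injected / in-domain / out-fluxed) is updated each step and must close.
#'
#' @param state simulation state as returned by [init_state()] or a
#'   previous call; carries `C`, `t`, and the ledger.
#' @param tensor diffusion-like tensor field for the model (R_drug or
#'   D_drug), n x 6, mm2/s.
#' @param porosity per-cell porosity.
#' @param source a `ced_source`.
#' @param dt time step, s (default 1).
#' @param n_steps number of steps.
#' @param face_avg face-averaging rule for `phi * tensor` conductances.
#' @return updated state.
#' @export
advance_concentration <- function(state, tensor, porosity, source, dt = 1,
                                  n_steps = 1, face_avg = "arithmetic") {
  stopifnot(dt > 0)
  mesh <- state$mesh
  tensor <- as_sym6_matrix(tensor)
  Q <- source_rate(source, state$t)
  key <- list(dt = dt, Q = Q, face_avg = face_avg)
  if (is.null(state$stepper) || !identical(state$stepper_key, key)) {
    state$stepper <- transport_stepper(mesh, state$flow, tensor, porosity,
                                       dt, source, Q, face_avg)
    state$stepper_key <- key
  }
  V <- mesh$cell_volume
  for (s in seq_len(n_steps)) {
    res <- state$stepper$step(state$C)
    state$C <- res$C
    state$t <- state$t + dt
    state$ledger$injected <- state$ledger$injected + res$injected
    state$ledger$outflux <- state$ledger$outflux + res$outflux
    neg <- min(state$C)
    tol_neg <- 1e-10 * max(1, max(abs(state$C)))
    if (neg < -tol_neg)
      stop("negative concentration beyond tolerance: min C = ", neg)
  }
  state$ledger$in_domain <- sum(porosity * V * state$C)
  tot <- state$ledger$injected
  state$ledger$closure <- if (tot > 0)
    (tot - state$ledger$in_domain - state$ledger$outflux) / tot else 0
  state
}

#' Initialize a simulation state
#'
#' @param mesh a `ced_mesh`.
#' @param flow a `ced_flow` from [solve_pressure()].
#' @param C0 initial concentration (default 0 everywhere).
#' @return list of class `ced_state` with `C`, `t = 0`, the flow field and
#'   an empty mass ledger.
#' @export
init_state <- function(mesh, flow, C0 = NULL) {
  if (is.null(C0)) C0 <- numeric(mesh$n_cells)
  stopifnot(length(C0) == mesh$n_cells)
  structure(list(mesh = mesh, flow = flow, C = C0, t = 0,
                 ledger = list(injected = 0, in_domain = 0, outflux = 0,
                               closure = 0),
                 stepper = NULL, stepper_key = NULL),
            class = "ced_state")
}

#' Run a full CED simulation
#'
#' Orchestrates the weakly coupled solve for one model: for each segment of
#' the infusion schedule the steady pressure/velocity field is solved, then
#' the transport equation is advanced at fixed velocity, recording
#' concentration snapshots and the mass ledger. Deterministic given its
#' inputs.
#'
#' @param mesh a `ced_mesh`.
#' @param model `"R"` (propagator-covariance model: effective permeability
#'   `T_drug`, diffusion tensor `R_drug`) or `"D"` (classical model:
#'   `K_drug`, `D_drug`).
#' @param drug a `ced_drugtensors` set from [build_drug_tensors()], or a
#'   list with elements `conductivity` and `tensor` to supply fields
#'   directly.
#' @param source a `ced_source`.
#' @param t_end infusion time to simulate, s.
#' @param dt transport time step, s (default 1).
#' @param snapshot_times times (s) at which to record C; always includes
#'   `t_end`. Snapshot times must be multiples of `dt`.
#' @param porosity per-cell porosity (defaults to `drug$porosity`).
#' @param face_avg face-averaging rule passed to the transport stepper.
#' @return object of class `ced_sim`: `model`, `times`, `C` (n_cells x
#'   n_snapshots matrix), `flow` (last segment), `ledger` (data frame per
#'   snapshot), `mesh`, `source`, `dt`.
#' @export
run_simulation <- function(mesh, model = c("R", "D"), drug, source, t_end,
                           dt = 1, snapshot_times = NULL,
                           porosity = NULL, face_avg = "arithmetic") {
  model <- match.arg(model)
  stopifnot(t_end >= 0)
  if (inherits(drug, "ced_drugtensors")) {
    cond <- if (model == "R") drug$T_drug else drug$K_drug
    tens <- if (model == "R") drug$R_drug else drug$D_drug
    if (is.null(porosity)) porosity <- drug$porosity
  } else {
    cond <- as_sym6_matrix(drug$conductivity)
    tens <- as_sym6_matrix(drug$tensor)
    if (is.null(porosity)) porosity <- drug$porosity
  }
  stopifnot(!is.null(porosity))
  snaps <- sort(unique(c(snapshot_times, t_end)))
  snaps <- snaps[snaps <= t_end]
  if (any(abs(snaps / dt - round(snaps / dt)) > 1e-9))
    stop("snapshot times must be multiples of dt")

  seg_bounds <- unique(c(source$schedule$time[source$schedule$time < t_end], t_end))
  Cmat <- matrix(0, mesh$n_cells, length(snaps))
  ledger <- NULL
  state <- NULL
  flow <- NULL
  si <- 1L
  t_cur <- 0
  if (length(snaps) && snaps[1] == 0) { # t_end = 0: initial state
    Cmat[, 1] <- 0
    ledger <- rbind(ledger, data.frame(time = 0, injected = 0, in_domain = 0,
                                       outflux = 0, closure = 0))
    si <- 2L
  }
  for (k in seq_len(length(seg_bounds))) {
    seg_end <- seg_bounds[k]
    if (seg_end <= t_cur) next
    flow <- solve_pressure(mesh, cond, source, t = t_cur)
    if (is.null(state)) state <- init_state(mesh, flow)
    else { state$flow <- flow; state$stepper <- NULL }
    while (t_cur < seg_end - 1e-9) {
      t_next <- if (si <= length(snaps)) min(snaps[si], seg_end) else seg_end
      n_steps <- round((t_next - t_cur) / dt)
      if (n_steps > 0)
        state <- advance_concentration(state, tens, porosity, source, dt,
                                       n_steps, face_avg)
      t_cur <- t_next
      if (si <= length(snaps) && abs(t_cur - snaps[si]) < 1e-9) {
        Cmat[, si] <- state$C
        ledger <- rbind(ledger, data.frame(time = t_cur,
                                           injected = state$ledger$injected,
                                           in_domain = state$ledger$in_domain,
                                           outflux = state$ledger$outflux,
                                           closure = state$ledger$closure))
        si <- si + 1L
      }
    }
  }
  structure(list(model = model, times = snaps, C = Cmat,
                 flow = flow, ledger = ledger, mesh = mesh,
                 source = source, dt = dt),
            class = "ced_sim")
}
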