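# Comparison analytics between the two models' concentration fields:
# fractional differences, distribution volumes, Bresenham path sums of the
# non-Gaussianity measure, correlations, paired tests, and the
# distribution-volume-vs-infused-volume relationship.

#' Voxelwise fractional concentration difference
#'
#' `f = (C_R - C_D) / C_D`, defined where the D-model concentration is at
#' least `floor` times its maximum (so `C_R = (f + 1) C_D` inside the
#' mask); elsewhere `NA`. Changing the floor changes only the mask, never
#' the `f` values inside it.
#'
#' @param CR,CD concentration vectors on the same cells.
#' @param floor relative concentration floor (default 1e-3; large enough
#'   to exclude numerical zeros but keeps the front of the spread, where
#'   fractional differences are largest).
#' @return numeric vector of `f`, with attribute `"floor"`.
#' @export
fractional_difference <- function(CR, CD, floor = 1e-3) {
  stopifnot(length(CR) == length(CD), floor > 0, floor < 1)
  thr <- floor * max(CD)
  f <- ifelse(CD >= thr & thr > 0, (CR - CD) / CD, NA_real_)
  attr(f, "floor") <- floor
  f
}

#' Distribution volume of the drug
#'
#' Volume of the cells in which the concentration reaches `fraction`
#' (default 5%) or more of the maximum concentration.
#'
#' @param C concentration per cell.
#' @param mesh the `ced_mesh` (supplies the cell volume).
#' @param fraction threshold as a fraction of `max(C)`, in (0, 1).
#' @return volume in mm3 (0 if `C` is identically zero).
#' @export
distribution_volume <- function(C, mesh, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  mx <- max(C)
  if (mx <= 0) return(0)
  sum(C >= fraction * mx) * mesh$cell_volume
}

#' 3-D Bresenham line between two voxels
#'
#' Integer digital line from `a` to `b` inclusive: a 26-connected monotone
#' voxel sequence of length `max(|delta|) + 1`. The driving axis is the
#' axis of largest absolute separation, with x > y > z precedence on ties;
#' error accumulators follow the classic integer algorithm.
#'
#' @param a,b integer voxel index triplets.
#' @return integer matrix (steps + 1) x 3, ordered from `a` to `b`.
#' @export
bresenham_line <- function(a, b) {
  a <- as.integer(round(a)); b <- as.integer(round(b))
  stopifnot(length(a) == 3, length(b) == 3)
  d <- b - a
  ad <- abs(d)
  s <- sign(d)
  n <- max(ad)
  out <- matrix(0L, n + 1, 3)
  out[1, ] <- a
  if (n == 0) return(out)
  drv <- which.max(ad)           # which.max ties -> lowest index: x > y > z
  oth <- setdiff(1:3, drv)
  err <- 2L * ad[oth] - ad[drv]
  cur <- a
  for (k in seq_len(n)) {
    cur[drv] <- cur[drv] + s[drv]
    for (m in 1:2) {
      if (err[m] > 0L) {
        cur[oth[m]] <- cur[oth[m]] + s[oth[m]]
        err[m] <- err[m] - 2L * ad[drv]
      }
      err[m] <- err[m] + 2L * ad[oth[m]]
    }
    out[k + 1, ] <- cur
  }
  out
}

#' Path sums of the non-Gaussianity measure along Bresenham lines
#'
#' For each target voxel, identifies the Bresenham voxel sequence from the
#' source voxel and sums the DC values of the voxels in the sequence — an
#' approximate, representative measure of the non-Gaussianity the fluid
#' encounters between the infusion site and the target (the digital line
#' is not the exact fluid path).
#'
#' @param dc per-voxel DC values as a 3-D array (`NA`/0 outside the mask).
#' @param source_voxel integer triplet; must be inside the mask (non-NA).
#' @param targets integer matrix n x 3 of target voxels.
#' @return numeric vector of path sums (mm2); out-of-mask voxels on a line
#'   contribute 0 and are counted in the `"n_outside"` attribute.
#' @export
path_dc_sum <- function(dc, source_voxel, targets) {
  stopifnot(length(dim(dc)) == 3)
  source_voxel <- as.integer(source_voxel)
  if (is.na(dc[source_voxel[1], source_voxel[2], source_voxel[3]]))
    stop("source voxel is outside the DC mask")
  targets <- matrix(as.integer(targets), ncol = 3)
  out <- numeric(nrow(targets))
  n_out <- 0L
  for (i in seq_len(nrow(targets))) {
    line <- bresenham_line(source_voxel, targets[i, ])
    vals <- dc[line]
    n_out <- n_out + sum(is.na(vals))
    out[i] <- sum(vals, na.rm = TRUE)
  }
  attr(out, "n_outside") <- n_out
  out
}

#' Correlation of |f| with the path-summed non-Gaussianity
#'
#' Pearson correlation (two-sided test) between the absolute fractional
#' concentration difference and the Bresenham path sum of DC over a voxel
#' mask (conventionally the distribution volume).
#'
#' @param f fractional differences (NA outside the f mask).
#' @param dc_sums path DC sums on the same cells.
#' @param mask logical vector selecting the voxels to correlate.
#' @return list with `r`, `p`, `n`; degenerate (zero-variance) input gives
#'   `r = NA` with `flagged = TRUE`.
#' @export
correlate_fdiff_dc <- function(f, dc_sums, mask = !is.na(f)) {
  keep <- mask & !is.na(f) & !is.na(dc_sums)
  x <- abs(f[keep]); y <- dc_sums[keep]
  if (sum(keep) < 3) stop("need at least 3 voxels to correlate")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(keep), flagged = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep), flagged = FALSE)
}

#' Paired t-test between the two models' concentrations
#'
#' Standard paired t on voxelwise `C_R - C_D` over a mask (conventionally
#' the union of the two models' distribution volumes).
#'
#' @param CR,CD concentrations on the same cells.
#' @param mask logical vector of voxels to include.
#' @return list with `t`, `p`, `n`, `mean_diff`; a degenerate
#'   (zero-variance, zero-mean) difference gives `t = 0`, `p = 1` with
#'   `flagged = TRUE`.
#' @export
paired_concentration_test <- function(CR, CD, mask = rep(TRUE, length(CR))) {
  stopifnot(length(CR) == length(CD))
  d <- (CR - CD)[mask]
  if (length(d) < 2) stop("need at least 2 paired voxels")
  if (sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                n = length(d), mean_diff = mean(d), flagged = TRUE))
  tt <- t.test(CR[mask], CD[mask], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, n = length(d),
       mean_diff = mean(d), flagged = FALSE)
}

#' Distribution volume vs infused volume linear fits
#'
#' Least-squares fit of distribution volume against infused volume,
#' separately per infusion rate; the relationship is expected to be close
#' to linear.
#'
#' @param series data frame with columns `rate` (label or ul/min),
#'   `infused` (mm3), `vd` (mm3); at least 3 points per rate.
#' @return data frame, one row per rate: `rate`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
dv_vs_infused <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("rate", "infused", "vd") %in% names(series)))
  out <- lapply(split(series, series$rate), function(s) {
    if (nrow(s) < 3) stop("need at least 3 points per rate for the linear fit")
    fit <- lm(vd ~ infused, data = s)
    rss <- sum(fit$residuals^2)
    tss <- sum((s$vd - mean(s$vd))^2)
    data.frame(rate = s$rate[1], slope = coef(fit)[2],
               intercept = coef(fit)[1],
               r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
               n = nrow(s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble a model-comparison report
#'
#' Convenience wrapper running the standard analytics between an R-model
#' and a D-model simulation at matched snapshot times: fractional
#' differences, distribution volumes, Bresenham DC path sums, the
#' |f| ~ sum(DC) correlation, and the paired t-test over the union of the
#' distribution volumes.
#'
#' @param simR,simD `ced_sim` objects with identical snapshot times.
#' @param dc per-cell DC values (mm2).
#' @param source_voxel integer triplet of the infusion voxel.
#' @param floor relative concentration floor for `f`.
#' @param fraction distribution-volume threshold fraction.
#' @return list of class `ced_report`: per-snapshot list with `time`, `f`,
#'   `vd_R`, `vd_D`, `correlation`, `paired`, plus `floor`, `fraction`.
#' @export
comparison_report <- function(simR, simD, dc, source_voxel,
                              floor = 1e-3, fraction = 0.05) {
  stopifnot(identical(simR$times, simD$times),
            identical(dim(simR$C), dim(simD$C)))
  mesh <- simR$mesh
  dc_arr <- array(NA_real_, mesh$shape)
  dc_arr[mesh$mask] <- dc
  targets <- mesh$coords
  sums <- path_dc_sum(dc_arr, source_voxel, targets)
  snaps <- lapply(seq_along(simR$times), function(k) {
    CR <- simR$C[, k]; CD <- simD$C[, k]
    f <- fractional_difference(CR, CD, floor)
    vdR <- distribution_volume(CR, mesh, fraction)
    vdD <- distribution_volume(CD, mesh, fraction)
    dvmask <- (max(CR) > 0 & CR >= fraction * max(CR)) |
              (max(CD) > 0 & CD >= fraction * max(CD))
    corr <- if (sum(!is.na(f) & dvmask) >= 3)
      correlate_fdiff_dc(f, sums, mask = dvmask) else NULL
    pt <- if (sum(dvmask) >= 2)
      paired_concentration_test(CR, CD, dvmask) else NULL
    list(time = simR$times[k], f = f, vd_R = vdR, vd_D = vdD,
         correlation = corr, paired = pt)
  })
  structure(list(snapshots = snaps, floor = floor, fraction = fraction,
                 dc_path_sums = sums),
            class = "ced_report")
}
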