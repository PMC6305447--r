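# Water -> drug calibration. The water tensors set the *shape* (eigenvectors
# and relative eigenvalues) of the drug transport tensors; tissue-specific
# calibration constants set their magnitude, and porosity is assigned per
# tissue class.

#' Calibration constants for drug tensors and porosity
#'
#' Magnitudes follow the CED modelling literature: a single diffusivity
#' scale `D_cal`, hydraulic-conductivity scales `K_cal` that are 100x larger
#' in white matter than in gray matter (fluid moves up to 100 times faster
#' along white-matter tracts), and porosities 0.21 (GM) / 0.19 (WM). CSF
#' values are not pinned down by that literature; the defaults treat CSF as
#' free-fluid-like (conductivity equal to white matter, porosity 0.9) to
#' avoid artificial barriers at ventricle boundaries, and are exposed here
#' precisely because they are a modelling choice.
#'
#' @param D_cal diffusivity scale applied to the normalized tensors.
#' @param K_cal named vector of conductivity scales for GM, WM, CSF.
#' @param porosity named vector of extracellular volume fractions.
#' @return list of class `ced_calibration`.
#' @export
calibration_constants <- function(D_cal = 1e-12,
                                  K_cal = c(GM = 0.013e-12, WM = 1.3e-12,
                                            CSF = 1.3e-12),
                                  porosity = c(GM = 0.21, WM = 0.19,
                                               CSF = 0.9)) {
  stopifnot(D_cal > 0, all(K_cal > 0),
            all(porosity > 0), all(porosity <= 1),
            all(c("GM", "WM", "CSF") %in% names(K_cal)),
            all(c("GM", "WM", "CSF") %in% names(porosity)))
  structure(list(D_cal = D_cal, K_cal = K_cal, porosity = porosity),
            class = "ced_calibration")
}

#' Eigen-decompose a tensor field and normalize eigenvalues by their mean
#'
#' Per voxel, the tensor is decomposed as `xi Lambda xi'`, eigenvalues are
#' divided by their average so the normalized eigenvalues mean to 1 exactly
#' (hence the normalized tensor has trace 3). Near-zero tensors are flagged
#' and mapped to the isotropic unit triple (1, 1, 1).
#'
#' @param tf SPD tensor field (n x 6 or single tensor).
#' @param eps mean-eigenvalue floor below which a voxel is treated as
#'   isotropic-unit.
#' @return list with `vectors` (3 x 3 x n), `values` (n x 3, normalized,
#'   descending), `mean` (n, the original eigenvalue averages), `flagged`
#'   (logical n).
#' @export
rescale_eigensystem <- function(tf, eps = 1e-300) {
  tf <- as_sym6_matrix(tf)
  e <- field_eigen(tf)
  mn <- rowMeans(e$values)
  flagged <- !is.finite(mn) | mn < eps
  vals <- e$values / mn
  vals[flagged, ] <- 1
  for (i in which(flagged)) e$vectors[, , i] <- diag(3)
  list(vectors = e$vectors, values = vals, mean = mn, flagged = flagged)
}

#' Build the drug transport tensors from the water tensors
#'
#' Applies the eigenvalue-normalization calibration: with
#' `xi_D Lambda_D xi_D'` the normalized eigensystem of the water diffusion
#' tensor and `xi_R Lambda_R xi_R'` that of the water covariance tensor,
#' \describe{
#'   \item{D_drug}{`D_cal * xi_D Lambda_D xi_D'` (drug diffusivity, D-model)}
#'   \item{K_drug}{`K_cal(tissue) * xi_D Lambda_D xi_D'` (conductivity, D-model)}
#'   \item{R_drug}{`D_cal * xi_R Lambda_R xi_R'` (drug diffusivity, R-model)}
#'   \item{T_drug}{`K_cal(tissue) * xi_R Lambda_R xi_R'` (effective
#'     permeability, R-model)}
#' }
#' so each drug tensor shares eigenvectors with its water parent and has
#' trace `3 * scale`.
#'
#' @param Dw,Rw water tensor fields (n x 6, mm2/s) over the in-mask voxels
#'   of `labels` (in `mask_idx` order).
#' @param labels a `ced_labels` object (or an integer vector of per-voxel
#'   tissue codes for the same n voxels).
#' @param consts a `ced_calibration` object.
#' @return list of class `ced_drugtensors` with fields `D_drug`, `K_drug`,
#'   `R_drug`, `T_drug` (n x 6), `porosity` (n), `label` (n).
#' @export
build_drug_tensors <- function(Dw, Rw, labels, consts = calibration_constants()) {
  Dw <- tensor_of(Dw); Rw <- tensor_of(Rw)
  lab <- if (inherits(labels, "ced_labels")) labels$labels[labels$labels > 0] else labels
  stopifnot(nrow(Dw) == nrow(Rw), nrow(Dw) == length(lab))
  if (any(!lab %in% LABEL_LEVELS[c("GM", "WM", "CSF")]))
    stop("voxel with unknown tissue label inside mask")
  tiss <- names(LABEL_LEVELS)[match(lab, LABEL_LEVELS)]
  kc <- unname(consts$K_cal[tiss])

  ed <- rescale_eigensystem(spd_repair(Dw))
  er <- rescale_eigensystem(spd_repair(Rw))
  shapeD <- field_from_eigen(ed$values, ed$vectors)
  shapeR <- field_from_eigen(er$values, er$vectors)

  structure(list(D_drug = consts$D_cal * shapeD,
                 K_drug = kc * shapeD,
                 R_drug = consts$D_cal * shapeR,
                 T_drug = kc * shapeR,
                 porosity = porosity_map(lab, consts),
                 label = lab),
            class = "ced_drugtensors")
}

#' Per-voxel porosity from tissue labels
#'
#' @param labels `ced_labels` object or integer vector of tissue codes.
#' @param consts a `ced_calibration` object.
#' @return numeric vector of extracellular volume fractions in (0, 1].
#' @export
porosity_map <- function(labels, consts = calibration_constants()) {
  lab <- if (inherits(labels, "ced_labels")) labels$labels[labels$labels > 0] else labels
  if (any(!lab %in% LABEL_LEVELS[c("GM", "WM", "CSF")]))
    stop("voxel with unknown tissue label inside mask")
  tiss <- names(LABEL_LEVELS)[match(lab, LABEL_LEVELS)]
  unname(consts$porosity[tiss])
}
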