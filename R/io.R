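# File formats: NIfTI volumes (scalar, label, symmetric-tensor and 4-D
# concentration series), the plain-text b-table, YAML run configuration,
# and JSON/CSV reports.

#' Write a symmetric tensor field as a 6-component NIfTI volume
#'
#' Components are stored along the 4th dimension in the fixed order
#' `xx, xy, xz, yy, yz, zz`; the order is recorded in a JSON sidecar next
#' to the file and checked on read.
#'
#' @param tensor n x 6 tensor field over the in-mask voxels.
#' @param mask_idx linear indices of the in-mask voxels.
#' @param shape grid shape (3 ints).
#' @param path output filename (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge, mm.
#' @export
write_tensor_nifti <- function(tensor, mask_idx, shape, path, voxel_size = 1.2) {
  tensor <- as_sym6_matrix(tensor)
  arr <- array(0, c(shape, 6))
  nvox <- prod(shape)
  for (k in 1:6) arr[mask_idx + (k - 1) * nvox] <- tensor[, k]
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(rep(voxel_size, 3), 1)
  RNifti::writeNifti(im, path)
  jsonlite::write_json(list(component_order = SYM6_NAMES,
                            voxel_size_mm = voxel_size),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a symmetric tensor field from a 6-component NIfTI volume
#'
#' @param path filename written by [write_tensor_nifti()].
#' @param mask_idx optional linear voxel indices to extract; default: all
#'   voxels with any non-zero component.
#' @return n x 6 matrix with attributes `shape`, `mask_idx`, `voxel_size`.
#' @export
read_tensor_nifti <- function(path, mask_idx = NULL) {
  im <- RNifti::readNifti(path)
  arr <- strip_nifti(im)
  if (length(dim(arr)) != 4 || dim(arr)[4] != 6)
    stop("not a 6-component tensor volume: ", path)
  vs <- RNifti::pixdim(im)[1]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!identical(meta$component_order, SYM6_NAMES))
      stop("unexpected tensor component order in ", sc)
    if (!is.null(meta$voxel_size_mm)) vs <- meta$voxel_size_mm
  }
  shape <- dim(arr)[1:3]
  nvox <- prod(shape)
  flat <- matrix(arr, nvox, 6, dimnames = list(NULL, SYM6_NAMES))
  if (is.null(mask_idx)) mask_idx <- which(rowSums(flat != 0) > 0)
  out <- flat[mask_idx, , drop = FALSE]
  attr(out, "shape") <- shape
  attr(out, "mask_idx") <- mask_idx
  attr(out, "voxel_size") <- vs
  out
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

# plain numeric array from a niftiImage (drop header attributes)
strip_nifti <- function(im) {
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write/read scalar or label volumes as NIfTI
#'
#' @param x 3-D array (scalar field or integer labels).
#' @param path filename.
#' @param voxel_size voxel edge, mm.
#' @export
write_scalar_nifti <- function(x, path, voxel_size = 1.2) {
  im <- RNifti::asNifti(x)
  RNifti::pixdim(im) <- rep(voxel_size, 3)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_scalar_nifti
#' @export
read_scalar_nifti <- function(path) {
  strip_nifti(RNifti::readNifti(path))
}

#' Write a 4-D concentration series as NIfTI with a time sidecar
#'
#' @param sim a `ced_sim` object.
#' @param path filename; snapshot times (s) go to a JSON sidecar.
#' @export
write_concentration_nifti <- function(sim, path) {
  mesh <- sim$mesh
  arr <- array(0, c(mesh$shape, ncol(sim$C)))
  nvox <- prod(mesh$shape)
  cells <- which(mesh$mask)
  for (k in seq_len(ncol(sim$C)))
    arr[cells + (k - 1) * nvox] <- sim$C[, k]
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(rep(mesh$h, 3), 1)
  RNifti::writeNifti(im, path)
  jsonlite::write_json(list(snapshot_times_s = sim$times, model = sim$model,
                            dt_s = sim$dt),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_concentration_nifti
#' @param mask logical array restricting which voxels become cells.
#' @return list with `C` (n_cells x n_snapshots), `times`, `shape`.
#' @export
read_concentration_nifti <- function(path, mask = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  shape <- dim(arr)[1:3]
  nvox <- prod(shape)
  if (is.null(mask)) mask <- array(TRUE, shape)
  cells <- which(mask)
  C <- matrix(0, length(cells), dim(arr)[4])
  for (k in seq_len(dim(arr)[4])) C[, k] <- arr[cells + (k - 1) * nvox]
  list(C = C, times = meta$snapshot_times_s, shape = shape,
       model = meta$model)
}

#' Write/read the acquisition as a plain-text b-table
#'
#' One line per volume: `b gx gy gz`, b in s/mm2.
#'
#' @param scheme a `ced_scheme`.
#' @param path filename.
#' @export
write_btable <- function(scheme, path) {
  m <- cbind(scheme$b, scheme$dirs)
  utils::write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_btable
#' @param delta diffusion time, s, to attach to the scheme.
#' @export
read_btable <- function(path, delta = 0.03) {
  m <- unname(as.matrix(utils::read.table(path)))
  b <- m[, 1]
  dirs <- m[, 2:4, drop = FALSE]
  nz <- b > 0
  nrm <- sqrt(rowSums(dirs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("non-unit gradient directions in b-table")
  structure(list(b = b, dirs = dirs, n_b0 = sum(!nz), delta = delta,
                 n_dirs = sum(b == unique(b[nz])[1]),
                 bvals = sort(unique(b[nz]))),
            class = "ced_scheme")
}

#' Check that volumes share a grid
#'
#' @param ... named 3-D/4-D arrays.
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  shapes <- lapply(vols, function(v) dim(v)[1:3])
  if (length(unique(lapply(shapes, paste, collapse = "x"))) > 1) {
    msg <- paste(sprintf("%s: %s", names(vols),
                         vapply(shapes, paste, "", collapse = "x")),
                 collapse = "; ")
    stop("input volumes are on different grids: ", msg)
  }
  invisible(TRUE)
}

#' Default run configuration
#'
#' Returns the full default configuration for the phantom-mode pipeline;
#' values from a YAML file are merged over these defaults by
#' [read_run_config()].
#'
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    phantom = list(shape = c(16L, 16L, 16L), preset = "default",
                   voxel_size = 1.2, delta = 0.03, noise_sigma = 0),
    scheme = list(n_dirs = 61L, bvals = c(1200, 2400), n_b0 = 1L),
    r_mode = "cumulant",
    calibration = list(D_cal = 1e-12,
                       K_cal = list(GM = 0.013e-12, WM = 1.3e-12, CSF = 1.3e-12),
                       porosity = list(GM = 0.21, WM = 0.19, CSF = 0.9)),
    source = list(voxel = NULL,    # default: a white-matter voxel near centre
                  rate_ul_min = 1.8, C_in = 1, p_b = 0, mode = "rate",
                  dp = 3500),
    solver = list(dt = 5, t_end = 600, snapshot_times = NULL,
                  face_avg = "arithmetic"),
    compare = list(floor = 1e-3, fraction = 0.05)
  )
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; missing entries fall back to
#'   [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(default_run_config(), cfg)
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Serialize a comparison report as JSON and CSV
#'
#' Writes `report.json` (summary per snapshot) and `report.csv` (one row
#' per time point: distribution volumes, correlation, paired test).
#'
#' @param report a `ced_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(report$snapshots, function(s) {
    data.frame(time_s = s$time, vd_R_mm3 = s$vd_R, vd_D_mm3 = s$vd_D,
               pearson_r = if (!is.null(s$correlation)) s$correlation$r else NA,
               pearson_p = if (!is.null(s$correlation)) s$correlation$p else NA,
               paired_t = if (!is.null(s$paired)) s$paired$t else NA,
               paired_p = if (!is.null(s$paired)) s$paired$p else NA,
               max_abs_f = suppressWarnings(max(abs(s$f), na.rm = TRUE)))
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(list(floor = report$floor, fraction = report$fraction,
                            snapshots = tab),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file.path(dir, "report.json"))
}
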