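# End-to-end phantom-mode pipeline and the command-line entry point.

#' Run the full phantom-mode pipeline
#'
#' Chains every stage: phantom generation (labels, propagators, signals),
#' tensor estimation (diffusion tensor fit and covariance-tensor
#' estimation), non-Gaussianity (DC) mapping, water-to-drug calibration,
#' the weakly coupled CFD solve for both the R-model and the D-model, and
#' the comparison analytics. Deterministic given the configuration.
#'
#' @param config configuration list as from [default_run_config()] /
#'   [read_run_config()].
#' @return list with all intermediate objects: `labels`, `scheme`, `prop`,
#'   `signals`, `Dw`, `Rw`, `dc`, `drug`, `mesh`, `source`, `simR`, `simD`,
#'   `report`, `source_voxel`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- merge_config(default_run_config(), config)
  ph <- cfg$phantom
  labels <- phantom_labels(ph$shape, ph$preset, ph$voxel_size, cfg$seed)
  scheme <- two_shell_scheme(cfg$scheme$n_dirs, unlist(cfg$scheme$bvals),
                             cfg$scheme$n_b0, ph$delta)
  prop <- phantom_propagators(labels, delta = ph$delta, seed = cfg$seed)
  signals <- phantom_signals(prop, scheme, noise_sigma = ph$noise_sigma,
                             seed = cfg$seed)
  dfit <- fit_diffusion_tensor(signals)
  rfit <- if (cfg$r_mode == "ground_truth")
    estimate_covariance_tensor(prop, mode = "ground_truth")
  else estimate_covariance_tensor(signals, mode = "cumulant")
  dc <- covariance_difference(rfit, dfit, delta = ph$delta)

  consts <- calibration_constants(cfg$calibration$D_cal,
                                  unlist(cfg$calibration$K_cal),
                                  unlist(cfg$calibration$porosity))
  drug <- build_drug_tensors(dfit, rfit, labels, consts)

  mesh <- build_mesh(labels$labels > 0, ph$voxel_size)
  src_vox <- cfg$source$voxel
  if (is.null(src_vox)) src_vox <- central_wm_voxel(labels)
  src_cell <- mesh$cell_id[src_vox[1], src_vox[2], src_vox[3]]
  if (src_cell == 0) stop("source voxel is outside the mesh mask")
  source <- source_spec(src_cell, rate_ul_min = cfg$source$rate_ul_min,
                        C_in = cfg$source$C_in, p_b = cfg$source$p_b,
                        mode = cfg$source$mode, dp = cfg$source$dp)

  sv <- cfg$solver
  simR <- run_simulation(mesh, "R", drug, source, sv$t_end, sv$dt,
                         unlist(sv$snapshot_times), face_avg = sv$face_avg)
  simD <- run_simulation(mesh, "D", drug, source, sv$t_end, sv$dt,
                         unlist(sv$snapshot_times), face_avg = sv$face_avg)
  report <- comparison_report(simR, simD, dc, src_vox,
                              floor = cfg$compare$floor,
                              fraction = cfg$compare$fraction)

  out <- list(labels = labels, scheme = scheme, prop = prop,
              signals = signals, Dw = dfit, Rw = rfit, dc = dc,
              drug = drug, mesh = mesh, source = source,
              source_voxel = src_vox, simR = simR, simD = simD,
              report = report, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

# in-mask white-matter voxel closest to the volume centre
central_wm_voxel <- function(labels) {
  wm <- which(labels$labels == LABEL_LEVELS[["WM"]])
  if (!length(wm)) stop("phantom has no white-matter voxels for the default source")
  co <- arrayInd(wm, labels$shape)
  ctr <- (labels$shape + 1) / 2
  d2 <- rowSums((sweep(co, 2, ctr))^2)
  co[which.min(d2), ]
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- res$labels$voxel_size
  shape <- res$labels$shape
  midx <- res$prop$mask_idx
  write_scalar_nifti(res$labels$labels, file.path(dir, "labels.nii.gz"), vs)
  write_tensor_nifti(res$Dw$tensor, midx, shape,
                     file.path(dir, "tensor_dw.nii.gz"), vs)
  write_tensor_nifti(res$Rw$tensor, midx, shape,
                     file.path(dir, "tensor_rw.nii.gz"), vs)
  dc_arr <- array(0, shape); dc_arr[midx] <- res$dc
  write_scalar_nifti(dc_arr, file.path(dir, "dc.nii.gz"), vs)
  por <- array(0, shape); por[midx] <- res$drug$porosity
  write_scalar_nifti(por, file.path(dir, "porosity.nii.gz"), vs)
  write_btable(res$scheme, file.path(dir, "btable.txt"))
  write_concentration_nifti(res$simR, file.path(dir, "conc_model_R.nii.gz"))
  write_concentration_nifti(res$simD, file.path(dir, "conc_model_D.nii.gz"))
  p_arr <- array(0, shape); p_arr[res$mesh$mask] <- res$simR$flow$p
  write_scalar_nifti(p_arr, file.path(dir, "pressure_model_R.nii.gz"), vs)
  write.csv(res$simR$ledger, file.path(dir, "ledger_model_R.csv"),
            row.names = FALSE)
  write.csv(res$simD$ledger, file.path(dir, "ledger_model_D.csv"),
            row.names = FALSE)
  write_report(res$report, dir)
  yaml::write_yaml(res$config, file.path(dir, "config_used.yaml"))
  outs <- list.files(dir, full.names = TRUE)
  manifest <- data.frame(file = basename(outs),
                         md5 = unname(tools::md5sum(outs)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `phantom`, `tensors`, `calibrate`, `simulate`, `compare`
#' (each runs the pipeline through the named stage) and `all` (the full
#' chain). Usage: `cedsim <subcommand> --config cfg.yaml [--out dir]`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit code, invisibly (0 on success).
#' @export
ced_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cedsim <phantom|tensors|calibrate|simulate|compare|all>",
    "--config <file.yaml> [--out <dir>]")
  stages <- c("phantom", "tensors", "calibrate", "simulate", "compare", "all")
  if (length(argv) < 1 || !(argv[1] %in% stages)) {
    message(usage)
    return(invisible(2L))
  }
  stage <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  if (!is.null(opts$err)) { message(opts$err, "\n", usage); return(invisible(2L)) }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else default_run_config()
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (is.null(cfg$out_dir)) cfg$out_dir <- "cedsim_out"

  status <- tryCatch({
    res <- run_stage(cfg, stage)
    message("cedsim ", stage, ": ok (seed ", cfg$seed, ", outputs in ",
            cfg$out_dir, ")")
    0L
  }, error = function(e) {
    message("cedsim ", stage, " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  out <- list(config = NULL, out = NULL, err = NULL)
  i <- 1
  while (i <= length(args)) {
    if (args[i] == "--config" && i < length(args)) {
      out$config <- args[i + 1]; i <- i + 2
    } else if (args[i] == "--out" && i < length(args)) {
      out$out <- args[i + 1]; i <- i + 2
    } else {
      out$err <- paste("unknown or incomplete argument:", args[i])
      return(out)
    }
  }
  out
}

# run the pipeline through the requested stage, writing stage outputs
run_stage <- function(cfg, stage) {
  if (stage %in% c("all", "simulate", "compare")) return(run_pipeline(cfg))
  ph <- cfg$phantom
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- phantom_labels(ph$shape, ph$preset, ph$voxel_size, cfg$seed)
  scheme <- two_shell_scheme(cfg$scheme$n_dirs, unlist(cfg$scheme$bvals),
                             cfg$scheme$n_b0, ph$delta)
  write_scalar_nifti(labels$labels, file.path(cfg$out_dir, "labels.nii.gz"),
                     ph$voxel_size)
  write_btable(scheme, file.path(cfg$out_dir, "btable.txt"))
  if (stage == "phantom") return(invisible(labels))
  prop <- phantom_propagators(labels, delta = ph$delta, seed = cfg$seed)
  signals <- phantom_signals(prop, scheme, noise_sigma = ph$noise_sigma,
                             seed = cfg$seed)
  dfit <- fit_diffusion_tensor(signals)
  rfit <- if (cfg$r_mode == "ground_truth")
    estimate_covariance_tensor(prop, mode = "ground_truth")
  else estimate_covariance_tensor(signals, mode = "cumulant")
  write_tensor_nifti(dfit$tensor, prop$mask_idx, labels$shape,
                     file.path(cfg$out_dir, "tensor_dw.nii.gz"), ph$voxel_size)
  write_tensor_nifti(rfit$tensor, prop$mask_idx, labels$shape,
                     file.path(cfg$out_dir, "tensor_rw.nii.gz"), ph$voxel_size)
  if (stage == "tensors") return(invisible(list(Dw = dfit, Rw = rfit)))
  consts <- calibration_constants(cfg$calibration$D_cal,
                                  unlist(cfg$calibration$K_cal),
                                  unlist(cfg$calibration$porosity))
  drug <- build_drug_tensors(dfit, rfit, labels, consts)
  por <- array(0, labels$shape); por[prop$mask_idx] <- drug$porosity
  write_scalar_nifti(por, file.path(cfg$out_dir, "porosity.nii.gz"),
                     ph$voxel_size)
  invisible(drug)
}
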