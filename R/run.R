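# Config-driven entry points: each command reads validated JSON config,
# runs the corresponding pipeline stage, and writes its primary outputs to
# files. Re-running a command on identical inputs and config produces
# byte-identical outputs.

read_json_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  need <- c("B", "W", "a0", "S")
  if (is.null(g) || !all(need %in% names(g)))
    stop("config must provide geometry {B, W, a0, S[, nu]}")
  specimen_geometry(g$B, g$W, g$a0, g$S, nu = if (is.null(g$nu)) 0.33 else g$nu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the tracking stage from a config
#'
#' Loads and preprocesses the frame sequence, synchronises it with the
#' mechanics CSV, tracks the whitening front and writes
#' `trajectory.csv` (plus optional QC difference frames) to the output
#' directory.
#'
#' @param config Path to a JSON config or an equivalent list. Recognised
#'   keys: `frames_dir`, `mech_csv`, `out_dir`, `stride`, `fps`, `gamma`,
#'   `window`, `mm_per_pixel` (or `supports_px` + `span_mm`),
#'   `notch_tip_px`, `roi`, `threshold`, `element_diameter_px`,
#'   `join_operator`, `displacement_mode`, `upsample_factor`,
#'   `qc_difference_frames`.
#' @return The `front_trajectory`, invisibly; primary output is
#'   `<out_dir>/trajectory.csv`.
#' @export
run_track <- function(config) {
  cfg <- if (is.character(config)) read_json_config(config) else config
  for (k in c("frames_dir", "mech_csv", "out_dir"))
    if (is.null(cfg[[k]])) stop(sprintf("config key '%s' is required", k))
  if (!file.exists(cfg$mech_csv)) stop(sprintf("mechanics CSV not found: %s", cfg$mech_csv))
  if (is.null(cfg$notch_tip_px)) stop("config key 'notch_tip_px' is required")

  fs <- load_frames(cfg$frames_dir, stride = cfg$stride %||% 15,
                    fps = cfg$fps %||% 60)
  fs <- preprocess_frames(fs, gamma = cfg$gamma %||% 1,
                          window = cfg$window %||% c(0, 100))
  mech <- read_mech_csv(cfg$mech_csv)
  synced <- sync_frames(fs, mech)
  cal <- if (!is.null(cfg$mm_per_pixel))
    calibrate(c(0, 0), c(0, cfg$span_mm %||% 1) / cfg$mm_per_pixel,
              cfg$span_mm %||% 1)
  else
    calibrate(cfg$supports_px[[1]], cfg$supports_px[[2]], cfg$span_mm)

  tr <- track_front(fs, synced, unlist(cfg$notch_tip_px), cal,
                    threshold = cfg$threshold %||% "otsu",
                    element_diameter_px = cfg$element_diameter_px %||% 2,
                    join_operator = cfg$join_operator %||% "closing",
                    roi = if (!is.null(cfg$roi)) unlist(cfg$roi) else NULL,
                    displacement_mode = cfg$displacement_mode %||% "euclidean",
                    upsample_factor = cfg$upsample_factor %||% 100)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_csv(tr, file.path(cfg$out_dir, "trajectory.csv"))
  if (isTRUE(cfg$qc_difference_frames))
    export_difference_frames(fs, file.path(cfg$out_dir, "qc_diff"),
                             cfg$upsample_factor %||% 100)
  invisible(tr)
}

#' Run R-curve assembly from a config
#'
#' Reads a tracked trajectory CSV, determines the modulus (supplied
#' `E_MPa`, or fitted from the record and corrected through a
#' notch-correction model JSON when given), assembles the R-curve and
#' writes `rcurve.csv` plus `rcurve_meta.json`.
#'
#' @param config Path to JSON config or list. Keys: `trajectory_csv`,
#'   `out_dir`, `geometry`, and optionally `E_MPa`, `eta`,
#'   `correction_model_json`.
#' @return The `rcurve`, invisibly.
#' @export
run_rcurve <- function(config) {
  cfg <- if (is.character(config)) read_json_config(config) else config
  for (k in c("trajectory_csv", "out_dir"))
    if (is.null(cfg[[k]])) stop(sprintf("config key '%s' is required", k))
  if (!file.exists(cfg$trajectory_csv))
    stop(sprintf("trajectory CSV not found: %s", cfg$trajectory_csv))
  geometry <- config_geometry(cfg)
  tr <- utils::read.csv(cfg$trajectory_csv)
  E <- cfg$E_MPa
  if (is.null(E)) {
    fit <- fit_linear_slope(tr$force_N[tr$synced], tr$disp_mm[tr$synced])
    Ef <- flexural_modulus(fit$m, geometry)
    model <- if (!is.null(cfg$correction_model_json))
      read_correction_json(cfg$correction_model_json) else NULL
    E <- correct_modulus(Ef, geometry$a0, model)
  }
  rc <- build_rcurve(tr, geometry, E = E, eta = cfg$eta %||% 1.9)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(rc),
                   file.path(cfg$out_dir, "rcurve.csv"), row.names = FALSE)
  meta <- list(geometry = unclass(geometry), E_MPa = E,
               eta = cfg$eta %||% 1.9,
               n_points = nrow(rc),
               software = paste0("whitefront ",
                                 as.character(utils::packageVersion("whitefront"))))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "rcurve_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rc)
}

#' Generate and write a synthetic scenario from a config
#'
#' @param config Path to JSON config or list; keys are
#'   [scenario_params()] arguments plus `out_dir` (and optionally a
#'   `geometry` block).
#' @return The scenario, invisibly.
#' @export
run_synth <- function(config) {
  cfg <- if (is.character(config)) read_json_config(config) else config
  if (is.null(cfg$out_dir)) stop("config key 'out_dir' is required")
  args <- cfg[setdiff(names(cfg), c("out_dir", "geometry"))]
  args <- args[names(args) %in% names(formals(scenario_params))]
  if (!is.null(cfg$geometry)) args$geometry <- config_geometry(cfg)
  sc <- synth_video(do.call(scenario_params, args))
  write_scenario(sc, cfg$out_dir)
  invisible(sc)
}

#' Regenerate the notch-correction model from a config
#'
#' Runs the plane-stress FE bend model at each requested notch length,
#' fits the second-order apparent-modulus polynomial and writes it as
#' JSON.
#'
#' @param config Path to JSON config or list. Keys: `geometry`,
#'   `a0_values_mm` (>= 3 values including 0), `out_json`, optionally
#'   `E_trial_MPa`, `elem_size_fine`, `elem_size_coarse`.
#' @return The `notch_correction` model, invisibly.
#' @export
run_fe_correct <- function(config) {
  cfg <- if (is.character(config)) read_json_config(config) else config
  if (is.null(cfg$out_json)) stop("config key 'out_json' is required")
  geometry <- config_geometry(cfg)
  a0s <- unlist(cfg$a0_values_mm %||% c(0, 0.075, 0.15, 0.3))
  if (length(unique(a0s)) < 3) stop("need at least 3 distinct a0 values")
  E_trial <- cfg$E_trial_MPa %||% 12000
  slopes <- vapply(a0s, function(a0) {
    mesh <- mesh_beam(geometry, a0 = a0,
                      elem_size_fine = cfg$elem_size_fine %||% 0.05,
                      elem_size_coarse = cfg$elem_size_coarse %||% 0.15)
    solve_bend(mesh, E_trial, geometry$nu)$m
  }, 0)
  model <- fit_correction(a0s, slopes, geometry)
  dir.create(dirname(cfg$out_json), recursive = TRUE, showWarnings = FALSE)
  write_correction_json(model, cfg$out_json)
  invisible(model)
}

#' Correlate tracked front and annotated crack propagation from a config
#'
#' @param config Path to JSON config or list. Keys: `trajectory_csv`,
#'   `annotations_csv`, `mm_per_pixel`, `out_json`.
#' @return The correlation report, invisibly.
#' @export
run_correlate <- function(config) {
  cfg <- if (is.character(config)) read_json_config(config) else config
  for (k in c("trajectory_csv", "annotations_csv", "mm_per_pixel", "out_json"))
    if (is.null(cfg[[k]])) stop(sprintf("config key '%s' is required", k))
  tr <- utils::read.csv(cfg$trajectory_csv)
  ann <- utils::read.csv(cfg$annotations_csv)
  cal <- calibrate(c(0, 0), c(0, 1 / cfg$mm_per_pixel), 1)
  agg <- aggregate_annotations(ann, cal)
  idx <- match(agg$frame_idx, tr$frame_idx)
  if (any(is.na(idx))) stop("annotated frames missing from the trajectory")
  res <- front_crack_correlation(tr$da_mono_mm[idx], agg$da_crack_mean_mm)
  dir.create(dirname(cfg$out_json), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(r = res$r, p = res$p, n = res$n,
                            lag_mean_mm = res$lag_mean_mm,
                            lag_sd_mm = res$lag_sd_mm),
                       cfg$out_json, auto_unbox = TRUE, digits = NA)
  invisible(res)
}
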