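#' Track the whitening front through a frame sequence
#'
#' Runs the per-frame pipeline of the whitening-front tracking algorithm:
#' the first retained frame (assumed free of whitening) is the
#' registration reference; every later frame is registered to it by
#' subpixel cross-correlation, the aligned reference is subtracted, the
#' difference is thresholded and cleaned morphologically inside the ROI,
#' and the front pixel is located. The front pixel is mapped back to
#' reference-frame coordinates by the estimated shift and snapped to the
#' pixel grid before the displacement from the notch tip is computed, so
#' that frame jitter does not leak into the displacement series.
#'
#' The per-frame threshold is global: either a fixed value, or (default)
#' Otsu's threshold computed on the final frame's difference image, which
#' carries the fully developed whitening zone.
#'
#' @param fs A [frame_sequence()] (preprocessed as desired).
#' @param synced Output of [sync_frames()] for `fs` (or `NULL`: frames
#'   are tracked without mechanics columns).
#' @param notch_tip_px `c(row, col)` of the initial notch tip, 1-based, in
#'   reference-frame coordinates.
#' @param calibration A [calibrate()] result.
#' @param threshold Fixed difference threshold in (0, 1), or `"otsu"`
#'   (default).
#' @param element_diameter_px,join_operator See [segment_whitening()].
#' @param roi `c(row_min, row_max, col_min, col_max)` region of interest
#'   around the notch (default: whole frame).
#' @param displacement_mode `"euclidean"` or `"vertical"`; see
#'   [locate_front()].
#' @param upsample_factor Registration precision, see [register_pair()].
#' @param min_peak_corr Frames whose registration confidence falls below
#'   this value are flagged as failed and carried with no front.
#' @return A data.frame of class `front_trajectory`, one row per retained
#'   frame: the synced columns plus `front_row`, `front_col` (reference
#'   coordinates; `NA` when no front), `da_raw_mm`, `da_mono_mm`
#'   (running maximum), `peak_corr`, `shift_dy`, `shift_dx`, `tracked`.
#'   Attribute `threshold` records the global threshold used.
#' @export
track_front <- function(fs, synced, notch_tip_px, calibration,
                        threshold = "otsu", element_diameter_px = 2,
                        join_operator = c("closing", "opening"),
                        roi = NULL, displacement_mode = c("euclidean", "vertical"),
                        upsample_factor = 100, min_peak_corr = 0.05) {
  stopifnot(inherits(fs, "frame_sequence"))
  join_operator <- match.arg(join_operator)
  displacement_mode <- match.arg(displacement_mode)
  n <- length(fs$frames)
  ref <- fs$frames[[1]]
  if (is.null(synced))
    synced <- data.frame(frame_idx = seq_len(n) - 1L,
                         original_index = fs$original_index,
                         t_s = frame_times(fs), force_N = NA_real_,
                         disp_mm = NA_real_, synced = TRUE)

  shifts <- vector("list", n)
  diffs <- vector("list", n)
  shifts[[1]] <- structure(list(dy = 0, dx = 0, peak_corr = 1),
                           class = "rigid_shift")
  diffs[[1]] <- matrix(0, nrow(ref), ncol(ref))
  for (i in seq_len(n)[-1]) {
    s <- tryCatch(register_pair(ref, fs$frames[[i]], upsample_factor),
                  error = function(e) NULL)
    if (!is.null(s) && s$peak_corr < min_peak_corr) s <- NULL
    shifts[[i]] <- s
    diffs[[i]] <- if (is.null(s)) NULL
      else difference_image(ref, fs$frames[[i]], s)
  }

  thr <- if (identical(threshold, "otsu")) {
    last_ok <- max(which(!vapply(diffs, is.null, TRUE)))
    d <- diffs[[last_ok]]
    if (!is.null(roi)) d <- d[roi[1]:roi[2], roi[3]:roi[4]]
    as.numeric(EBImage::otsu(EBImage::Image(d), range = c(0, 1)))
  } else as.numeric(threshold)

  front_row <- front_col <- rep(NA_real_, n)
  da_raw <- numeric(n)
  pc <- dy <- dx <- rep(NA_real_, n)
  tracked <- logical(n)
  for (i in seq_len(n)) {
    s <- shifts[[i]]
    if (is.null(s)) next
    tracked[i] <- TRUE
    pc[i] <- s$peak_corr; dy[i] <- s$dy; dx[i] <- s$dx
    if (i == 1) next
    mask <- segment_whitening(diffs[[i]], thr, element_diameter_px,
                              join_operator, roi = roi)
    fr <- locate_front(mask, notch_tip_px, calibration, displacement_mode)
    if (is.null(fr)) next
    # back to reference coordinates, snapped to the pixel grid
    px <- round(c(fr$pixel[1] - s$dy, fr$pixel[2] - s$dx))
    front_row[i] <- px[1]; front_col[i] <- px[2]
    da_raw[i] <- front_displacement(px, notch_tip_px, calibration,
                                    displacement_mode)
  }

  out <- cbind(synced,
               data.frame(front_row = front_row, front_col = front_col,
                          da_raw_mm = da_raw, da_mono_mm = cummax(da_raw),
                          peak_corr = pc, shift_dy = dy, shift_dx = dx,
                          tracked = tracked))
  structure(out, threshold = thr, displacement_mode = displacement_mode,
            class = c("front_trajectory", "data.frame"))
}

front_displacement <- function(px, notch_tip_px, calibration, mode) {
  d <- if (mode == "euclidean")
    sqrt(sum((px - notch_tip_px)^2))
  else
    max(0, notch_tip_px[1] - px[1])
  d * calibration$mm_per_pixel
}

#' Write a front trajectory as CSV
#'
#' @param trajectory A [track_front()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  cols <- c("frame_idx", "original_index", "t_s", "force_N", "disp_mm",
            "synced", "front_row", "front_col", "da_raw_mm", "da_mono_mm",
            "peak_corr")
  utils::write.csv(as.data.frame(trajectory)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Export difference images for visual quality control
#'
#' Recomputes the registered difference image for each frame and writes
#' it as a PNG sequence (a subtraction video), mirroring the visual check
#' used to confirm that segmentation follows the whitening zone.
#'
#' @param fs A [frame_sequence()].
#' @param dir Output directory.
#' @param upsample_factor See [register_pair()].
#' @return `dir`, invisibly.
#' @export
export_difference_frames <- function(fs, dir, upsample_factor = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- fs$frames[[1]]
  for (i in seq_along(fs$frames)) {
    d <- if (i == 1) matrix(0, nrow(ref), ncol(ref))
    else difference_image(ref, fs$frames[[i]],
                          register_pair(ref, fs$frames[[i]], upsample_factor))
    png::writePNG(pmin(1, pmax(0, d)),
                  file.path(dir, sprintf("diff_%04d.png", i - 1L)))
  }
  invisible(dir)
}
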