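#' Construct a frame sequence
#'
#' A frame sequence is an ordered list of 2-D grayscale matrices (row 1 at
#' the image top) together with the capture frame rate, the subsampling
#' stride and, per retained frame, the 0-based index the frame had in the
#' captured video. The elapsed time of a retained frame is
#' `original_index / fps`.
#'
#' @param frames List of numeric matrices with identical dimensions,
#'   intensities in `[0, 1]`.
#' @param fps Capture frame rate, frames per second.
#' @param stride Subsampling factor: one of every `stride` captured frames
#'   is retained.
#' @param original_index Integer vector, 0-based indices of the retained
#'   frames in the captured video. Defaults to `(seq_along(frames) - 1) *
#'   stride`.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 60, stride = 1,
                           original_index = (seq_along(frames) - 1L) * stride) {
  if (length(frames) == 0) stop("empty frame sequence")
  if (fps <= 0) stop("fps must be positive")
  if (stride < 1) stop("stride must be >= 1")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes")
  if (length(original_index) != length(frames))
    stop("original_index length must match the number of frames")
  if (any(diff(original_index) <= 0))
    stop("original_index must be strictly increasing")
  structure(list(frames = frames, fps = fps, stride = as.integer(stride),
                 original_index = as.integer(original_index)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frames of %dx%d px, %g fps, stride %d\n",
              length(x$frames), d[1], d[2], x$fps, x$stride))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Frame elapsed times
#'
#' @param fs A [frame_sequence()].
#' @return Numeric vector of per-frame elapsed times in seconds,
#'   `original_index / fps`.
#' @export
frame_times <- function(fs) fs$original_index / fs$fps

rgb_to_gray <- function(a) {
  # ITU-R BT.601 luminance weights, the convention used by most grayscale
  # conversions of video material
  if (length(dim(a)) == 2) return(a)
  if (dim(a)[3] >= 3)
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  a[, , 1]
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF frames")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported frame format '%s' (use PNG or TIFF)", ext)))
  m <- rgb_to_gray(a)
  # readPNG/readTIFF already return [0,1] doubles for integer inputs
  m[m < 0] <- 0; m[m > 1] <- 1
  m
}

#' Load and subsample a captured image sequence
#'
#' Reads a directory of numbered grayscale (or colour, converted to
#' luminance) PNG/TIFF frames, retaining one of every `stride` frames,
#' starting with frame 0. Files are taken in lexicographic order, so frame
#' numbers should be zero-padded.
#'
#' @param source Directory containing the frames.
#' @param stride Subsampling factor (default 15: at 60 fps this retains 4
#'   frames per second, which resolves the front propagation while keeping
#'   the registration cost modest).
#' @param fps Capture frame rate of the source video (default 60).
#' @return A [frame_sequence()].
#' @export
load_frames <- function(source, stride = 15, fps = 60) {
  if (!dir.exists(source)) stop(sprintf("unreadable source '%s'", source))
  files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0) stop("empty sequence: no PNG/TIFF frames found")
  if (stride < 1) stop("stride must be >= 1")
  keep <- seq(1, length(files), by = stride)
  frames <- lapply(files[keep], read_frame_file)
  frame_sequence(frames, fps = fps, stride = stride,
                 original_index = as.integer(keep - 1L))
}

#' Intensity preprocessing: percentile windowing and gamma correction
#'
#' Each frame is linearly rescaled so that the `window[1]` and `window[2]`
#' intensity percentiles map to 0 and 1 (values outside are clipped), then
#' raised to the power `gamma`. This standardises the appearance across
#' frames before registration and subtraction. A constant-intensity frame
#' has a degenerate window and is returned as all zeros with a warning.
#'
#' @param fs A [frame_sequence()].
#' @param gamma Gamma exponent, must be positive. Default 1 (off).
#' @param window Length-2 numeric, lower/upper percentiles in `[0, 100]`.
#'   Default `c(1, 99)`.
#' @return A [frame_sequence()] with transformed frames.
#' @export
preprocess_frames <- function(fs, gamma = 1, window = c(1, 99)) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (gamma <= 0) stop("gamma must be positive")
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 100))
    stop("window percentiles must satisfy 0 <= low < high <= 100")
  fs$frames <- lapply(fs$frames, function(f) {
    q <- stats::quantile(f, window / 100, names = FALSE)
    if (q[2] <= q[1]) {
      warning("constant-intensity frame: degenerate window, returning zeros")
      return(array(0, dim(f)))
    }
    g <- (f - q[1]) / (q[2] - q[1])
    g[g < 0] <- 0; g[g > 1] <- 1
    if (gamma != 1) g <- g^gamma
    g
  })
  fs
}

#' Read tester mechanics channels from CSV
#'
#' The tester records force, load-line displacement and elapsed time as
#' columns of one acquisition record (one row per sample, shared sample
#' index). Expected header: `time_s, force_N, disp_mm`.
#'
#' @param path CSV file path.
#' @return A data.frame of class `mech_channels`.
#' @export
read_mech_csv <- function(path) {
  d <- utils::read.csv(path)
  mech_channels(d$time_s, d$force_N, d$disp_mm)
}

#' Construct a mechanics-channel record
#'
#' @param time_s,force_N,disp_mm Equal-length numeric vectors; `time_s`
#'   must be non-decreasing.
#' @return A data.frame of class `mech_channels`.
#' @export
mech_channels <- function(time_s, force_N, disp_mm) {
  if (is.null(time_s) || is.null(force_N) || is.null(disp_mm))
    stop("mechanics record needs time_s, force_N and disp_mm")
  n <- length(time_s)
  if (length(force_N) != n || length(disp_mm) != n)
    stop("mechanics channels must have equal lengths")
  if (any(diff(time_s) < 0)) stop("time_s must be non-decreasing")
  structure(data.frame(time_s = time_s, force_N = force_N,
                       disp_mm = disp_mm),
            class = c("mech_channels", "data.frame"))
}

#' Synchronise retained frames with the mechanics channels
#'
#' Each retained frame is stamped with its elapsed time
#' `original_index / fps` (camera and tester start together), and force and
#' displacement are linearly interpolated at that time over the shared
#' acquisition index. Interpolating both channels in time on the common
#' record is equivalent to the force-matching description of the
#' synchronisation pre-peak, and stays well defined after peak load where
#' force is no longer monotonic. Frames whose time falls outside the
#' mechanics record are flagged `synced = FALSE` (their force/displacement
#' are `NA`) and are excluded from R-curve assembly.
#'
#' @param fs A [frame_sequence()].
#' @param mech A [mech_channels()] record.
#' @return A data.frame with one row per retained frame: `frame_idx`
#'   (0-based retained index), `original_index`, `t_s`, `force_N`,
#'   `disp_mm`, `synced`.
#' @export
sync_frames <- function(fs, mech) {
  stopifnot(inherits(fs, "frame_sequence"))
  t <- frame_times(fs)
  inside <- t >= min(mech$time_s) & t <= max(mech$time_s)
  f <- stats::approx(mech$time_s, mech$force_N, xout = t, ties = "ordered")$y
  d <- stats::approx(mech$time_s, mech$disp_mm, xout = t, ties = "ordered")$y
  if (any(!inside))
    warning(sprintf("%d frame(s) beyond the mechanics record are unsynced",
                    sum(!inside)))
  data.frame(frame_idx = seq_along(t) - 1L,
             original_index = fs$original_index,
             t_s = t, force_N = f, disp_mm = d, synced = inside)
}
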