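# Phenomenological forward model of a whitening-front bend test. It
# renders what the tracking pipeline assumes about real videos -- a bright
# damage halo nucleating at the notch tip and growing toward the top
# surface, an optional darker crack line lagging the front by a constant
# offset, rigid frame jitter, sensor noise -- together with a
# load-displacement record that is linear until the front reaches the top
# surface and softens smoothly afterwards. It is a test harness, not a
# bone-fracture simulator.

#' Parameters of a synthetic whitening-front scenario
#'
#' Defaults describe a miniature human SE(B) specimen viewed through a
#' 128 x 128 px region of interest at 10 um/px: W = 0.9 mm (90 px),
#' a0 = 0.35 mm, span 6.15 mm, loaded at 0.01 mm/s and captured at 60 fps
#' with one of every 15 frames emitted. The whitening halo amplitude is
#' ten times the sensor noise. Jitter is modelled as whole-pixel frame
#' displacements (stage/readout steps) with `P(+/-1 px) = 0.045` per axis,
#' i.e. a per-frame jitter standard deviation of 0.3 px; the registration
#' stage is validated on continuous subpixel shifts separately.
#'
#' @param geometry A [specimen_geometry()].
#' @param img_shape `c(rows, cols)` of the rendered frames.
#' @param mm_per_pixel Image scale, mm/px.
#' @param fps Capture frame rate (frames/s).
#' @param frame_stride The emitted sequence keeps one of every
#'   `frame_stride` captured frames; emitted frame `i` (0-based) has
#'   original index `i * frame_stride`.
#' @param n_frames Number of emitted frames.
#' @param onset_frame Emitted-frame index at which whitening nucleates.
#' @param front_speed_px Front advance per emitted frame, px (integer).
#' @param crack_lag_mm Constant distance by which the crack tip lags the
#'   whitening front, mm. Default 0.35; `NULL` draws one value per
#'   scenario uniformly from [0.3, 0.4].
#' @param crack_visible Render the crack as a dark 1-px line (rat-tibia
#'   style); if `FALSE` (default, miniature-SE(B) style) the crack exists
#'   in the ground truth but is not visible.
#' @param amplitude Whitening halo intensity increase (0 disables
#'   whitening).
#' @param noise_sd Additive Gaussian sensor noise, intensity units.
#' @param jitter_sd Per-axis jitter standard deviation, px.
#' @param jitter_integer If `TRUE` (default) jitter shifts are whole
#'   pixels with `P(+/-1) = jitter_sd^2 / 2`; if `FALSE` they are drawn
#'   continuously from `N(0, jitter_sd)` and rendered by bilinear
#'   resampling, which smears the halo edge by up to half a pixel --
#'   the harder, fully general case.
#' @param halo_halfwidth_max Maximum halo halfwidth, px.
#' @param halo_below_px Halo extent below the notch tip, px.
#' @param loading_rate Crosshead speed, mm/s.
#' @param E Material Young's modulus, MPa.
#' @param mech_hz Mechanics acquisition rate, Hz.
#' @param softening_tau_s Time constant of the post-peak load decay, s.
#' @param seed RNG seed; a fixed seed makes the scenario bit-reproducible.
#' @return List of class `scenario_params`.
#' @export
scenario_params <- function(geometry = specimen_geometry(B = 0.9, W = 0.9,
                                                         a0 = 0.35, S = 6.15,
                                                         nu = 0.33),
                            img_shape = c(128, 128),
                            mm_per_pixel = 0.01,
                            fps = 60, frame_stride = 15, n_frames = 100,
                            onset_frame = 5, front_speed_px = 1,
                            crack_lag_mm = 0.35, crack_visible = FALSE,
                            amplitude = 0.5, noise_sd = 0.05,
                            jitter_sd = 0.3, jitter_integer = TRUE,
                            halo_halfwidth_max = 12, halo_below_px = 10,
                            loading_rate = 0.01, E = 12000,
                            mech_hz = 20, softening_tau_s = 5,
                            seed = 42) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  if (amplitude > 0 && amplitude <= noise_sd)
    stop("halo amplitude must exceed the noise level")
  if (is.null(crack_lag_mm)) {
    set.seed(seed + 1L)
    crack_lag_mm <- stats::runif(1, 0.3, 0.4)
  }
  if (crack_lag_mm < 0) stop("crack lag must be >= 0")
  p <- list(geometry = geometry, img_shape = as.integer(img_shape),
            mm_per_pixel = mm_per_pixel, fps = fps,
            frame_stride = as.integer(frame_stride),
            n_frames = as.integer(n_frames),
            onset_frame = onset_frame, front_speed_px = front_speed_px,
            crack_lag_mm = crack_lag_mm, crack_visible = crack_visible,
            amplitude = amplitude, noise_sd = noise_sd,
            jitter_sd = jitter_sd, jitter_integer = jitter_integer,
            halo_halfwidth_max = halo_halfwidth_max,
            halo_below_px = halo_below_px,
            loading_rate = loading_rate, E = E, mech_hz = mech_hz,
            softening_tau_s = softening_tau_s, seed = seed)
  # derived layout: beam centred vertically, notch at the centre column
  W_px <- round(geometry$W / mm_per_pixel)
  a0_px <- round(geometry$a0 / mm_per_pixel)
  if (W_px + 4 > img_shape[1])
    stop("image too small for the specimen width at this scale")
  p$row_top <- (img_shape[1] - W_px) %/% 2 + 1L
  p$row_bot <- p$row_top + W_px - 1L
  p$col_notch <- img_shape[2] %/% 2
  p$row_tip <- p$row_bot - a0_px
  p$da_max_px <- W_px - a0_px
  p$notch_tip_px <- c(p$row_tip, p$col_notch)
  p$roi <- c(max(1L, p$row_top - 3L), p$row_bot,
             max(1L, p$col_notch - 20L), min(img_shape[2], p$col_notch + 20L))
  class(p) <- "scenario_params"
  p
}

# Monotone front schedule in whole pixels per emitted frame (0-based
# frame index); clipped at the ligament with a warning if it overshoots.
front_schedule_px <- function(p) {
  i <- seq_len(p$n_frames) - 1L
  da <- pmax(0, (i - p$onset_frame) * p$front_speed_px)
  if (max(da) > p$da_max_px) da <- pmin(da, p$da_max_px)
  da
}

# Emitted-frame elapsed times, s.
scenario_times <- function(p) (seq_len(p$n_frames) - 1L) * p$frame_stride / p$fps

# Generator's beam model: stiffness consistent with the notched-section
# flexural relation, so that an analysis of the record recovers E exactly.
scenario_stiffness <- function(p) {
  g <- p$geometry
  4 * p$E * g$B * (g$W - g$a0)^3 / g$S^3
}

#' Synthetic mechanics channels
#'
#' Displacement grows at the loading rate; force rises linearly with the
#' scenario stiffness until the emitted frame at which the front schedule
#' reaches the top surface (ligament consumed), then decays exponentially
#' -- a smooth softening to near-zero load with no unstable fracture. The
#' record is sampled at `mech_hz` on a grid that contains every emitted
#' frame time, so frame-time interpolation is exact at the knots.
#'
#' @param params A [scenario_params()].
#' @return A [mech_channels()] record.
#' @export
synth_mechanics <- function(params) {
  p <- params
  da <- front_schedule_px(p)
  times <- scenario_times(p)
  i_div <- which(da >= p$da_max_px)[1]
  t_div <- if (is.na(i_div)) Inf else times[i_div]
  dt <- 1 / p$mech_hz
  fi <- p$frame_stride / p$fps
  stopifnot(abs(dt * round(fi / dt) - fi) < 1e-9)  # knots hit frame times
  t <- seq(0, max(times) + 1, by = dt)
  m <- scenario_stiffness(p)
  d <- p$loading_rate * t
  F_ <- ifelse(t <= t_div, m * d,
               m * p$loading_rate * t_div * exp(-(t - t_div) / p$softening_tau_s))
  mech_channels(t, F_, d)
}

render_frame <- function(p, speckle, da_px, da_crack_px, jy, jx) {
  nr <- p$img_shape[1]; nc <- p$img_shape[2]
  img <- matrix(0.05, nr, nc)
  # specimen band, shifted rigidly by the frame jitter
  rows <- (p$row_top:p$row_bot) + jy
  cols <- seq_len(nc)  # beam spans the full view horizontally
  ok <- rows >= 1 & rows <= nr
  # speckle texture moves with the specimen
  src_r <- (p$row_top:p$row_bot)[ok]
  src_c <- ((cols - jx - 1) %% nc) + 1
  img[rows[ok], ] <- speckle[src_r, src_c]
  tip_r <- p$row_tip + jy; tip_c <- p$col_notch + jx
  # machined notch: dark slot from the bottom face to the tip
  notch_rows <- (p$row_tip:p$row_bot) + jy
  nok <- notch_rows >= 1 & notch_rows <= nr & tip_c >= 1 & tip_c <= nc
  img[notch_rows[nok], tip_c] <- 0.02
  if (da_px > 0 && p$amplitude > 0) {
    r_f <- tip_r - da_px
    r_lo <- min(tip_r + p$halo_below_px, p$row_bot + jy)
    for (r in r_f:r_lo) {
      if (r < 1 || r > nr) next
      # halfwidth 2 at the tip keeps the top row robust to single-pixel
      # noise under morphological opening; it widens one px per row below
      w <- min(p$halo_halfwidth_max, 2 + (r - r_f))
      cl <- max(1, tip_c - w); cu <- min(nc, tip_c + w)
      img[r, cl:cu] <- pmin(1, img[r, cl:cu] + p$amplitude)
    }
  }
  if (p$crack_visible && da_crack_px > 0 && tip_c >= 1 && tip_c <= nc) {
    cr <- (tip_r - da_crack_px):tip_r
    cok <- cr >= 1 & cr <= nr
    img[cr[cok], tip_c] <- pmax(0, img[cr[cok], tip_c] - 0.3)
  }
  img
}

#' Render a synthetic whitening-front video with ground truth
#'
#' Generates the emitted frame sequence (speckled specimen, growing
#' whitening halo, optional crack line, whole-pixel jitter, Gaussian
#' noise) plus the per-frame ground truth and the forward-computed
#' reference R-curve. The halo is a solid intensity step whose top row
#' tapers to a 3-px-wide tip directly above the notch: the top-most
#' above-threshold pixel of a noise-free rendering is exactly the
#' programmed front.
#'
#' The speckle is clipped to `[0.1, 0.5]` so that adding the default halo
#' amplitude never saturates the sensor range: the difference image then
#' steps by the full amplitude at the front.
#'
#' @param params A [scenario_params()].
#' @return List of class `synthetic_scenario`: `frames`
#'   (a [frame_sequence()]), `mech`, `truth` (data.frame: `frame_idx`,
#'   `t_s`, `da_true_mm`, `da_crack_mm`, `front_row`, `front_col`,
#'   `jitter_dy`, `jitter_dx`), `reference_rcurve`
#'   (see [build_rcurve()]), `calibration`, `params`.
#' @export
synth_video <- function(params) {
  p <- params
  set.seed(p$seed)
  nr <- p$img_shape[1]; nc <- p$img_shape[2]

  # band-limited speckle: smoothed white noise, fixed mean and contrast
  raw <- matrix(stats::runif(nr * nc), nr, nc)
  k <- stats::dnorm(-3:3, sd = 1.2); k <- k / sum(k)
  sm <- t(apply(apply(raw, 2, function(v) stats::filter(v, k, circular = TRUE)),
                1, function(v) stats::filter(v, k, circular = TRUE)))
  sm <- (sm - mean(sm)) / stats::sd(sm)
  speckle <- pmin(pmax(0.3 + 0.08 * sm, 0.1), 0.5)

  da <- front_schedule_px(p)
  lag_px <- round(p$crack_lag_mm / p$mm_per_pixel)
  da_crack <- pmax(0, da - lag_px)
  jit <- if (p$jitter_integer) {
    pm1 <- min(0.45, p$jitter_sd^2 / 2)  # var of a +/-1 step pair = 2 * p
    matrix(sample(c(-1, 0, 1), 2L * p$n_frames, replace = TRUE,
                  prob = c(pm1, 1 - 2 * pm1, pm1)), ncol = 2)
  } else {
    matrix(stats::rnorm(2L * p$n_frames, 0, p$jitter_sd), ncol = 2)
  }
  jit[1, ] <- 0  # the reference frame defines the lab frame

  frames <- vector("list", p$n_frames)
  for (i in seq_len(p$n_frames)) {
    ji <- round(jit[i, ])
    img <- render_frame(p, speckle, da[i], da_crack[i], ji[1], ji[2])
    resid <- jit[i, ] - ji
    if (any(resid != 0)) {
      img <- shift_image(img, resid[1], resid[2])
      img[is.na(img)] <- 0.05  # background
    }
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    frames[[i]] <- pmin(pmax(img, 0), 1)
  }
  fs <- frame_sequence(frames, fps = p$fps, stride = p$frame_stride)

  cal <- calibrate(c(p$row_bot, p$col_notch - p$geometry$S / 2 / p$mm_per_pixel),
                   c(p$row_bot, p$col_notch + p$geometry$S / 2 / p$mm_per_pixel),
                   span_mm = p$geometry$S)

  truth <- data.frame(
    frame_idx = seq_len(p$n_frames) - 1L,
    t_s = scenario_times(p),
    da_true_mm = da * p$mm_per_pixel,
    da_crack_mm = da_crack * p$mm_per_pixel,
    front_row = ifelse(da > 0, p$row_tip - da + jit[, 1], NA_integer_),
    front_col = ifelse(da > 0, p$col_notch + jit[, 2], NA_integer_),
    jitter_dy = jit[, 1], jitter_dx = jit[, 2])

  mech <- synth_mechanics(p)
  synced <- sync_frames(fs, mech)
  ref_traj <- cbind(synced,
                    data.frame(da_raw_mm = truth$da_true_mm,
                               da_mono_mm = cummax(truth$da_true_mm)))
  # frames after the front exits the top surface are truncated by design,
  # so the a >= W warning carries no information here
  reference <- suppressWarnings(
    build_rcurve(ref_traj, p$geometry, E = p$E, m = scenario_stiffness(p)))

  structure(list(frames = fs, mech = mech, truth = truth,
                 reference_rcurve = reference, calibration = cal,
                 params = p),
            class = "synthetic_scenario")
}

#' Write a synthetic scenario to disk
#'
#' Writes `frames/frame_0000.png` ..., `mech.csv`, `truth.csv` and
#' `scenario.json` (geometry, scale, notch tip, ROI and the recommended
#' analysis configuration) under `dir`.
#'
#' @param scenario A [synth_video()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  s <- scenario; p <- s$params
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(s$frames$frames))
    png::writePNG(s$frames$frames[[i]],
                  file.path(dir, "frames", sprintf("frame_%04d.png", i - 1L)))
  utils::write.csv(data.frame(time_s = s$mech$time_s,
                              force_N = s$mech$force_N,
                              disp_mm = s$mech$disp_mm),
                   file.path(dir, "mech.csv"), row.names = FALSE)
  utils::write.csv(s$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- list(
    geometry = p$geometry[c("B", "W", "a0", "S", "nu")],
    mm_per_pixel = p$mm_per_pixel,
    # the emitted sequence is already subsampled: stride 1 at the
    # effective rate keeps t = original_index / fps correct
    stride = 1L, fps = p$fps / p$frame_stride,
    notch_tip_px = p$notch_tip_px, roi = p$roi,
    threshold = 0.6 * p$amplitude, element_diameter_px = 2,
    join_operator = "opening", displacement_mode = "vertical",
    upsample_factor = 100,
    E_MPa = p$E, seed = p$seed)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
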