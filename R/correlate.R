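# Association between whitening-front propagation and crack-tip
# propagation. The crack end points come from repeated manual annotations
# (supplied as a CSV so the statistic is computable headlessly); the
# statistic is Pearson's r between the front displacement series and the
# per-frame mean crack extension.

#' Aggregate repeated crack annotations
#'
#' Each repetition marks, per frame, the beginning (pre-notch) and end of
#' the visible crack; the crack extension is the Euclidean pixel distance
#' between the two, scaled to mm. Repetitions must cover the same frames.
#'
#' @param annotations Data.frame with columns `frame_idx`, `repetition`,
#'   `start_row`, `start_col`, `end_row`, `end_col` (pixel coordinates).
#' @param calibration A [calibrate()] result.
#' @return Data.frame of class `crack_annotations`: `frame_idx`,
#'   `n_rep`, `da_crack_mean_mm`, `da_crack_sd_mm` (`NA` when fewer than
#'   2 repetitions).
#' @export
aggregate_annotations <- function(annotations, calibration) {
  need <- c("frame_idx", "repetition", "start_row", "start_col",
            "end_row", "end_col")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  sp <- split(annotations, annotations$repetition)
  frames <- sort(unique(annotations$frame_idx))
  for (r in sp)
    if (!identical(sort(unique(r$frame_idx)), frames))
      stop("mismatched frame sets across repetitions")
  d_mm <- sqrt((annotations$end_row - annotations$start_row)^2 +
               (annotations$end_col - annotations$start_col)^2) *
          calibration$mm_per_pixel
  agg_m <- tapply(d_mm, annotations$frame_idx, mean)
  agg_n <- tapply(d_mm, annotations$frame_idx, length)
  agg_s <- tapply(d_mm, annotations$frame_idx, function(v)
    if (length(v) >= 2) stats::sd(v) else NA_real_)
  structure(data.frame(frame_idx = as.integer(names(agg_m)),
                       n_rep = as.integer(agg_n),
                       da_crack_mean_mm = as.numeric(agg_m),
                       da_crack_sd_mm = as.numeric(agg_s)),
            class = c("crack_annotations", "data.frame"))
}

#' Correlation between whitening-front and crack propagation
#'
#' Pearson's r between the paired displacement series, with the two-sided
#' p value from the exact t transform on n - 2 degrees of freedom, plus
#' the mean and standard deviation of the per-frame front-minus-crack
#' offset (the distance by which the whitening front runs ahead of the
#' crack tip).
#'
#' @param front_da_mm Whitening-front displacement series, mm.
#' @param crack_da_mm Paired crack-extension series (typically the
#'   annotation mean), mm.
#' @return List of class `front_crack_correlation`: `r`, `p`, `n`,
#'   `lag_mean_mm`, `lag_sd_mm`. A zero-variance series gives `r = NA`
#'   with `degenerate = TRUE`.
#' @export
front_crack_correlation <- function(front_da_mm, crack_da_mm) {
  stopifnot(length(front_da_mm) == length(crack_da_mm))
  n <- length(front_da_mm)
  if (n < 3) stop("need at least 3 paired samples")
  lag <- front_da_mm - crack_da_mm
  degenerate <- stats::sd(front_da_mm) == 0 || stats::sd(crack_da_mm) == 0
  if (degenerate) {
    r <- NA_real_; pval <- NA_real_
  } else {
    r <- stats::cor(front_da_mm, crack_da_mm)
    if (abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    } else pval <- 0
  }
  structure(list(r = r, p = pval, n = n,
                 lag_mean_mm = mean(lag), lag_sd_mm = stats::sd(lag),
                 degenerate = degenerate),
            class = "front_crack_correlation")
}

#' @export
print.front_crack_correlation <- function(x, ...) {
  cat(sprintf("front-crack correlation: r = %.4f (p = %.3g, n = %d), lag %.3f +/- %.3f mm\n",
              x$r, x$p, x$n, x$lag_mean_mm, x$lag_sd_mm))
  invisible(x)
}

#' Simulate annotation repetitions from ground truth
#'
#' Utility for testing and synthetic studies: turns a true crack-extension
#' series into `n_rep` noisy click repetitions (start at the notch tip,
#' end at the crack tip, both perturbed by isotropic Gaussian pixel
#' noise).
#'
#' @param truth Data.frame with `frame_idx` and `da_crack_mm`.
#' @param notch_tip_px `c(row, col)` of the pre-notch click target.
#' @param calibration A [calibrate()] result.
#' @param n_rep Number of repetitions (default 5).
#' @param click_sd_px Std. dev. of the click error, px (default 5).
#' @return Annotations data.frame suitable for
#'   [aggregate_annotations()].
#' @export
simulate_annotations <- function(truth, notch_tip_px, calibration,
                                 n_rep = 5, click_sd_px = 5) {
  da_px <- truth$da_crack_mm / calibration$mm_per_pixel
  out <- do.call(rbind, lapply(seq_len(n_rep), function(rep) {
    n <- nrow(truth)
    data.frame(frame_idx = truth$frame_idx, repetition = rep,
               start_row = notch_tip_px[1] + stats::rnorm(n, 0, click_sd_px),
               start_col = notch_tip_px[2] + stats::rnorm(n, 0, click_sd_px),
               end_row = notch_tip_px[1] - da_px + stats::rnorm(n, 0, click_sd_px),
               end_col = notch_tip_px[2] + stats::rnorm(n, 0, click_sd_px))
  }))
  rownames(out) <- NULL
  out
}
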