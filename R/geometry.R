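#' Specimen geometry for a single-edge notched bend SE(B) test
#'
#' Bundles the dimensions of a three-point-bend specimen. All lengths are in
#' millimetres; the notch is assumed to sit at midspan on the tensile
#' (bottom) face and the crack propagates through the width `W`.
#'
#' @param B Specimen thickness (out-of-plane), mm.
#' @param W Specimen width in the bending direction (the crack path length),
#'   mm.
#' @param a0 Initial notch length, mm. Must satisfy `0 <= a0 < W` (an
#'   un-notched beam, `a0 = 0`, is allowed for modulus work).
#' @param S Support span, mm.
#' @param nu Poisson ratio, dimensionless. Default 0.33, a standard value
#'   for cortical bone.
#' @return An object of class `specimen_geometry` (a named list).
#' @examples
#' g <- specimen_geometry(B = 0.9, W = 0.9, a0 = 0.35, S = 6.15)
#' @export
specimen_geometry <- function(B, W, a0, S, nu = 0.33) {
  stopifnot(is.numeric(B), is.numeric(W), is.numeric(a0), is.numeric(S))
  if (B <= 0 || W <= 0 || S <= 0)
    stop("B, W and S must be positive")
  if (a0 < 0 || a0 >= W)
    stop("a0 must lie in [0, W)")
  if (nu <= 0 || nu >= 0.5)
    stop("nu must lie in (0, 0.5)")
  structure(list(B = B, W = W, a0 = a0, S = S, nu = nu),
            class = "specimen_geometry")
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf(
    "SE(B) geometry: B = %g mm, W = %g mm, a0 = %g mm, S = %g mm, nu = %g\n",
    x$B, x$W, x$a0, x$S, x$nu))
  invisible(x)
}

#' Pixel-size calibration from the support contact points
#'
#' The two support contact points visible in the first frame are a known
#' physical distance apart (the support span), which fixes the image scale.
#' The scale is the span divided by the Euclidean pixel distance between the
#' two points.
#'
#' @param left_support_px,right_support_px Numeric length-2 vectors
#'   `c(row, col)` of the two support contact points (0-based or 1-based is
#'   immaterial; only their difference is used).
#' @param span_mm Physical distance between the two points, mm.
#' @return An object of class `calibration` with fields `mm_per_pixel`,
#'   `left_support_px`, `right_support_px`, `span_mm`.
#' @examples
#' cal <- calibrate(c(400, 100), c(400, 715), span_mm = 6.15)
#' cal$mm_per_pixel  # 0.01
#' @export
calibrate <- function(left_support_px, right_support_px, span_mm) {
  stopifnot(length(left_support_px) == 2, length(right_support_px) == 2)
  if (span_mm <= 0) stop("span_mm must be positive")
  d <- sqrt(sum((as.numeric(left_support_px) -
                 as.numeric(right_support_px))^2))
  if (d == 0) stop("degenerate calibration: support points coincide")
  structure(list(mm_per_pixel = span_mm / d,
                 left_support_px = as.numeric(left_support_px),
                 right_support_px = as.numeric(right_support_px),
                 span_mm = span_mm),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.6g mm/px (span %g mm)\n",
              x$mm_per_pixel, x$span_mm))
  invisible(x)
}
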