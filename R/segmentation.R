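#' Disc-shaped structuring element
#'
#' Binary structuring element containing every pixel offset whose Euclidean
#' distance from the centre is at most `diameter / 2`. A diameter of 2
#' yields the 4-connected cross; larger diameters approach a filled disc.
#'
#' @param diameter_px Disc diameter in pixels, >= 1.
#' @return 0/1 matrix of odd side length.
#' @export
disc_element <- function(diameter_px) {
  if (diameter_px < 1) stop("element diameter must be >= 1")
  r <- diameter_px / 2
  n <- 2L * floor(r) + 1L
  off <- seq_len(n) - (floor(r) + 1L)
  k <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  storage.mode(k) <- "integer"
  k
}

#' Segment the whitening region of a difference image
#'
#' Thresholds the difference image and applies a morphological operator
#' with a disc element. The default operator is *closing*
#' (dilation-then-erosion), which joins neighbouring whitening patches by
#' filling small dark islands between them; *opening*
#' (erosion-then-dilation) is available instead and additionally removes
#' isolated above-threshold specks, at the price of not bridging gaps.
#'
#' An empty mask is a valid result (no whitening yet).
#'
#' @param diff Numeric difference image (from [difference_image()]).
#' @param threshold Scalar in (0, 1); pixels with `diff >= threshold` are
#'   whitening candidates.
#' @param element_diameter_px Disc diameter for the morphological step,
#'   default 2.
#' @param join_operator `"closing"` (default) or `"opening"`.
#' @param roi Optional `c(row_min, row_max, col_min, col_max)` (1-based,
#'   inclusive) restricting segmentation to a rectangular region of
#'   interest around the notch; pixels outside are forced to background.
#' @return Object of class `whitening_mask`: integer 0/1 matrix with
#'   attributes `threshold`, `element_diameter_px`, `join_operator`.
#' @export
segment_whitening <- function(diff, threshold, element_diameter_px = 2,
                              join_operator = c("closing", "opening"),
                              roi = NULL) {
  join_operator <- match.arg(join_operator)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  m <- matrix(as.integer(diff >= threshold), nrow(diff), ncol(diff))
  if (!is.null(roi)) {
    keep <- matrix(0L, nrow(m), ncol(m))
    keep[roi[1]:roi[2], roi[3]:roi[4]] <- 1L
    m <- m * keep
  }
  k <- disc_element(element_diameter_px)
  m <- if (join_operator == "closing")
    EBImage::erode(EBImage::dilate(m, k), k)
  else
    EBImage::dilate(EBImage::erode(m, k), k)
  if (!is.null(roi)) m <- m * keep  # closing can dilate past the ROI edge
  structure(m, threshold = threshold,
            element_diameter_px = element_diameter_px,
            join_operator = join_operator, class = "whitening_mask")
}

#' Locate the whitening front in a segmented mask
#'
#' The front is taken from the top-most (minimum-row) occupied row of the
#' mask: its left-most and right-most pixels are the top-left and top-right
#' extrema of the whitening region, and the front is whichever of the two
#' lies farther from the initial notch tip (ties broken toward the
#' top-left). The front displacement is the distance from the notch tip
#' converted to millimetres: either the Euclidean pixel distance
#' (`mode = "euclidean"`) or the vertical (row) projection
#' (`mode = "vertical"`, the through-width crack-extension reading).
#'
#' @param mask A `whitening_mask` (or any 0/1 matrix).
#' @param notch_tip_px `c(row, col)` of the initial notch tip (1-based).
#' @param calibration A [calibrate()] result.
#' @param mode Distance convention, `"euclidean"` (default) or
#'   `"vertical"`.
#' @return `NULL` if the mask is empty, else a list with `pixel`
#'   (`c(row, col)`) and `displacement_mm`.
#' @export
locate_front <- function(mask, notch_tip_px, calibration,
                         mode = c("euclidean", "vertical")) {
  mode <- match.arg(mode)
  occ <- which(mask != 0, arr.ind = TRUE)
  if (nrow(occ) == 0) return(NULL)
  top <- min(occ[, 1])
  cols <- occ[occ[, 1] == top, 2]
  cand <- rbind(c(top, min(cols)), c(top, max(cols)))
  d <- sqrt((cand[, 1] - notch_tip_px[1])^2 + (cand[, 2] - notch_tip_px[2])^2)
  pick <- if (d[2] > d[1]) 2L else 1L  # tie -> top-left
  px <- cand[pick, ]
  dp <- if (mode == "euclidean") d[pick] else max(0, notch_tip_px[1] - px[1])
  list(pixel = px, displacement_mm = dp * calibration$mm_per_pixel)
}
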