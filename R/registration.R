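# Signed DFT frequency indices 0, 1, ..., -1 in FFT storage order.
fft_freq_idx <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n) - floor(n / 2)
}

# Upsampled portion of the inverse DFT of X by matrix multiplication.
# Computes the inverse DFT on a (nor x noc) output grid with spacing
# 1/usfac px, whose top-left sample sits at (-roff, -coff)/usfac px.
# This is the single-step "matrix-multiply DFT" used to refine the
# cross-correlation peak without inverse-transforming a huge zero-padded
# array.
dft_upsample <- function(X, nor, noc, usfac, roff, coff) {
  nr <- nrow(X); nc <- ncol(X)
  kernc <- exp((-2i * pi / (nc * usfac)) *
                 outer(fft_freq_idx(nc), (0:(noc - 1)) - coff))
  kernr <- exp((-2i * pi / (nr * usfac)) *
                 outer((0:(nor - 1)) - roff, fft_freq_idx(nr)))
  kernr %*% X %*% kernc
}

#' Subpixel rigid registration of two frames
#'
#' Estimates the rigid translation `(dy, dx)` mapping the reference frame
#' onto the current frame (i.e. `current(r, c) ~ reference(r - dy, c - dx)`)
#' by cross-correlation in the Fourier domain, refined to `1 / upsample_factor`
#' pixel by a single-step upsampled DFT evaluated only in a 1.5 px
#' neighbourhood of the integer-pixel peak. Only translation is estimated;
#' the specimen geometry is not deformed.
#'
#' Frame means are subtracted before correlation so that the (large) DC
#' component does not flatten the correlation peak.
#'
#' @param reference,current Numeric matrices of identical dimensions.
#' @param upsample_factor Integer >= 1; the shift is resolved to
#'   `1/upsample_factor` px. Default 100.
#' @return An object of class `rigid_shift`: list with `dy`, `dx` (px,
#'   subpixel) and `peak_corr`, the normalised correlation peak in
#'   `[0, 1]`.
#' @export
register_pair <- function(reference, current, upsample_factor = 100) {
  stopifnot(is.matrix(reference), is.matrix(current))
  if (!all(dim(reference) == dim(current)))
    stop("reference and current frames must have equal shapes")
  if (upsample_factor < 1) stop("upsample_factor must be >= 1")
  nr <- nrow(reference); nc <- ncol(reference)

  r0 <- reference - mean(reference)
  c0 <- current - mean(current)
  if (sum(r0^2) == 0 || sum(c0^2) == 0)
    stop("no texture to register: zero-variance image")

  F1 <- stats::fft(r0)
  F2 <- stats::fft(c0)
  CP <- F2 * Conj(F1)

  cc <- stats::fft(CP, inverse = TRUE) / (nr * nc)
  acc <- Mod(cc)
  pk <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  peak_val <- acc[pk[1], pk[2]]

  if (upsample_factor > 1) {
    us <- upsample_factor
    dy0 <- round(dy * us) / us
    dx0 <- round(dx * us) / us
    nbh <- ceiling(us * 1.5)
    off <- floor(nbh / 2)
    # dft_upsample carries the forward-transform sign, so hand it the
    # conjugate spectrum to sample the inverse transform (the correlation)
    cc_up <- dft_upsample(Conj(CP), nbh, nbh, us,
                          off - dy0 * us, off - dx0 * us) / (nr * nc)
    aup <- Mod(cc_up)
    pk2 <- which(aup == max(aup), arr.ind = TRUE)[1, ]
    dy <- dy0 + (pk2[1] - 1 - off) / us
    dx <- dx0 + (pk2[2] - 1 - off) / us
    peak_val <- aup[pk2[1], pk2[2]]
  }

  denom <- sqrt(sum(r0^2) * sum(c0^2))
  structure(list(dy = as.numeric(dy), dx = as.numeric(dx),
                 peak_corr = min(1, as.numeric(peak_val / denom))),
            class = "rigid_shift")
}

#' @export
print.rigid_shift <- function(x, ...) {
  cat(sprintf("rigid shift: dy = %.4f px, dx = %.4f px (peak corr %.3f)\n",
              x$dy, x$dx, x$peak_corr))
  invisible(x)
}

#' Resample an image by a (subpixel) rigid shift
#'
#' Returns the image evaluated at `(r - dy, c - dx)` by bilinear
#' interpolation, i.e. the content is moved *down* by `dy` rows and *right*
#' by `dx` columns. Output pixels whose source coordinates fall outside the
#' input are `NA` (border invalidation).
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in rows/columns (may be fractional).
#' @return Numeric matrix of the same size, `NA` at invalidated borders.
#' @export
shift_image <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr) - dy
  c <- seq_len(nc) - dx
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- matrix(NA_real_, nr, nc)
  # when the fractional part is exactly zero the +1 neighbour has zero
  # weight, so reuse the base index; this lets integer shifts reach the
  # last row/column
  r1 <- ifelse(fr == 0, r0, r0 + 1)
  c1 <- ifelse(fc == 0, c0, c0 + 1)
  rok <- which(r0 >= 1 & r1 <= nr)
  cok <- which(c0 >= 1 & c1 <= nc)
  if (length(rok) == 0 || length(cok) == 0) return(out)
  A <- img[r0[rok], c0[cok], drop = FALSE]
  B <- img[r0[rok], c1[cok], drop = FALSE]
  C <- img[r1[rok], c0[cok], drop = FALSE]
  D <- img[r1[rok], c1[cok], drop = FALSE]
  wr <- fr[rok]; wc <- fc[cok]
  out[rok, cok] <-
    (1 - wr) %o% (1 - wc) * A + (1 - wr) %o% wc * B +
    wr %o% (1 - wc) * C + wr %o% wc * D
  out
}

#' Whitening-enhancing difference image
#'
#' The reference frame is resampled by the registered shift so that it is
#' aligned with the current frame, then subtracted from it. Whitening is an
#' intensity *increase*, so negative differences are clipped to zero.
#' Border pixels invalidated by the resampling are set to zero.
#'
#' @param reference,current Numeric matrices of identical dimensions.
#' @param shift A `rigid_shift` from [register_pair()] (or any list with
#'   `dy`, `dx`).
#' @return Numeric matrix, the clipped difference `current - aligned
#'   reference`.
#' @export
difference_image <- function(reference, current, shift) {
  stopifnot(all(dim(reference) == dim(current)))
  if (!is.finite(shift$dy) || !is.finite(shift$dx))
    stop("invalid shift")
  ref_al <- shift_image(reference, shift$dy, shift$dx)
  d <- current - ref_al
  d[is.na(d)] <- 0
  d[d < 0] <- 0
  d
}
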