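# Independent brute-force oracles, kept deliberately naive.

# Morphology with the same border convention as the pipeline: the
# structuring-element neighbourhood is clipped at the image boundary
# (out-of-bounds counts as foreground for erosion, background for
# dilation).
kernel_offsets <- function(k) {
  ctr <- (dim(k) + 1) %/% 2
  w <- which(k != 0, arr.ind = TRUE)
  cbind(w[, 1] - ctr[1], w[, 2] - ctr[2])
}

brute_erode <- function(m, k) {
  off <- kernel_offsets(k)
  out <- matrix(0L, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
    out[r, c] <- as.integer(all(m[cbind(rr[ok], cc[ok])] != 0))
  }
  out
}

brute_dilate <- function(m, k) {
  off <- kernel_offsets(k)
  out <- matrix(0L, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
    out[r, c] <- as.integer(any(m[cbind(rr[ok], cc[ok])] != 0))
  }
  out
}

brute_open <- function(m, k) brute_dilate(brute_erode(m, k), k)
brute_close <- function(m, k) brute_erode(brute_dilate(m, k), k)

# Shoelace polygon area for a closed vertex list (x, y).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Independent transcription of the E1820 SE(B) geometry function,
# written term by term rather than as one expression.
seb_f_reference <- function(x) {
  num_poly <- 1.99 - x * (1 - x) * (2.15 - 3.93 * x + 2.70 * x^2)
  num <- 3 * x^0.5 * num_poly
  den <- 2 * (1 + 2 * x) * (1 - x)^(3 / 2)
  num / den
}

# Band-limited random texture plus an analytic Fourier subpixel shift.
make_texture <- function(n, seed) {
  set.seed(seed)
  k <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)
  g <- exp(-outer(k^2, k^2, "+") / (2 * (n / 6)^2))
  Re(stats::fft(stats::fft(matrix(stats::runif(n * n), n, n)) * g,
                inverse = TRUE)) / (n * n)
}

fourier_shift <- function(img, dy, dx) {
  n <- nrow(img)
  k <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)
  ph <- exp(-2i * pi * outer(k * dy, k * dx, "+") / n)
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n * n)
}
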