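cal <- calibrate(c(0, 0), c(0, 100), 1)  # 0.01 mm/px

test_that("identical repetitions aggregate with zero spread", {
  ann <- do.call(rbind, lapply(1:5, function(r)
    data.frame(frame_idx = 0:2, repetition = r,
               start_row = 50, start_col = 32,
               end_row = c(50, 40, 30), end_col = 32)))
  agg <- aggregate_annotations(ann, cal)
  expect_equal(agg$da_crack_mean_mm, c(0, 0.1, 0.2))
  expect_equal(agg$da_crack_sd_mm, c(0, 0, 0))
  expect_equal(agg$n_rep, c(5L, 5L, 5L))
})

test_that("mean and sd follow hand arithmetic", {
  # repetitions measuring 1.0, 1.1, 0.9 mm at one frame
  ann <- data.frame(frame_idx = 0, repetition = 1:3,
                    start_row = 100, start_col = 0,
                    end_row = 100 - c(100, 110, 90), end_col = 0)
  agg <- aggregate_annotations(ann, cal)
  expect_equal(agg$da_crack_mean_mm, 1.0)
  expect_equal(agg$da_crack_sd_mm, 0.1)
})

test_that("mismatched frame sets across repetitions are rejected", {
  ann <- data.frame(frame_idx = c(0, 1, 0), repetition = c(1, 1, 2),
                    start_row = 0, start_col = 0, end_row = 1, end_col = 1)
  expect_error(aggregate_annotations(ann, cal), "mismatched")
})

test_that("noisy click repetitions average within the standard-error bound", {
  set.seed(21)
  # crack extensions well clear of zero, where the Euclidean distance of
  # noisy clicks is unbiased to first order
  truth <- data.frame(frame_idx = 0:399,
                      da_crack_mm = seq(0.4, 1.2, length.out = 400))
  ann <- simulate_annotations(truth, c(150, 64), cal, n_rep = 5,
                              click_sd_px = 5)
  agg <- aggregate_annotations(ann, cal)
  err_px <- (agg$da_crack_mean_mm - truth$da_crack_mm) / cal$mm_per_pixel
  # axial click error enters through both end points: the 5-rep mean has
  # standard error sqrt(2) * 5 / sqrt(5) px
  se <- sqrt(2) * 5 / sqrt(5)
  expect_lt(abs(mean(err_px)), 1)          # unbiased (to first order)
  expect_gt(mean(abs(err_px) <= 2 * se), 0.9)  # ~95 % inside 2 SE
  expect_lt(stats::sd(err_px), 1.5 * se)
})

test_that("a constant offset gives perfect correlation and the programmed lag", {
  front <- seq(0, 0.5, by = 0.01)
  res <- front_crack_correlation(front, front - 0.4)
  expect_equal(res$r, 1)
  expect_equal(res$lag_mean_mm, 0.4)
  expect_equal(res$lag_sd_mm, 0)
  expect_lt(res$p, 0.001)
  rev <- front_crack_correlation(front, -front)
  expect_equal(rev$r, -1)
})

test_that("Pearson r is invariant to affine rescaling of either series", {
  set.seed(4)
  a <- cumsum(stats::runif(30)); b <- a + stats::rnorm(30, 0, 0.2)
  r0 <- front_crack_correlation(a, b)$r
  expect_equal(front_crack_correlation(a * 100, b)$r, r0)       # mm -> px
  expect_equal(front_crack_correlation(a, b * 3 + 7)$r, r0)
})

test_that("zero-variance series are flagged degenerate", {
  res <- front_crack_correlation(rep(1, 10), seq_len(10))
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
})

test_that("the p value matches the exact t transform", {
  set.seed(6)
  x <- stats::rnorm(20); y <- x + stats::rnorm(20)
  res <- front_crack_correlation(x, y)
  expect_equal(res$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("the estimated r concentrates on the population value", {
  set.seed(31)
  rho <- 0.97; n <- 60
  rs <- replicate(300, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    front_crack_correlation(x, y)$r
  })
  expect_lt(abs(mean(rs) - rho), 0.01)
})
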