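test_that("a fixed seed reproduces the scenario bit for bit", {
  p <- small_scenario_params(seed = 42)
  a <- synth_video(p); b <- synth_video(p)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth, b$truth)
  expect_identical(a$mech, b$mech)
})

test_that("a noise-free jitter-free rendering returns the programmed front exactly", {
  p <- small_scenario_params(noise_sd = 0, jitter_sd = 0)
  sc <- synth_video(p)
  thr <- p$amplitude / 2
  for (i in seq_len(p$n_frames)) {
    da_true_px <- sc$truth$da_true_mm[i] / p$mm_per_pixel
    if (da_true_px == 0) next
    diffm <- sc$frames$frames[[i]] - sc$frames$frames[[1]]
    top <- min(which(apply(diffm >= thr, 1, any)))
    expect_equal(p$row_tip - top, da_true_px)
  }
})

test_that("the crack lags the front by the programmed constant distance", {
  p <- small_scenario_params(crack_lag_mm = 0.3)
  sc <- synth_video(p)
  lag <- sc$truth$da_true_mm - sc$truth$da_crack_mm
  grown <- sc$truth$da_crack_mm > 0
  expect_true(all(abs(lag[grown] - 0.3) < 1e-9))
  expect_true(all(sc$truth$da_crack_mm >= 0))
  # unspecified lag is drawn once per scenario from 0.3-0.4 mm
  p2 <- small_scenario_params(seed = 5, crack_lag_mm = NULL)
  expect_gte(p2$crack_lag_mm, 0.3)
  expect_lte(p2$crack_lag_mm, 0.4)
})

test_that("the load-displacement record is linear until the front reaches the surface", {
  p <- small_scenario_params()
  sc <- synth_video(p)
  m <- 4 * p$E * p$geometry$B * (p$geometry$W - p$geometry$a0)^3 / p$geometry$S^3
  i_div <- which(sc$truth$da_true_mm >= p$geometry$W - p$geometry$a0)[1]
  t_div <- sc$truth$t_s[i_div]
  pre <- sc$mech$time_s <= t_div & sc$mech$time_s > 0
  expect_true(all(abs(sc$mech$force_N[pre] / sc$mech$disp_mm[pre] - m) < 1e-12 * m))
  # softening afterwards: continuous and monotonically declining
  post <- sc$mech$time_s >= t_div
  expect_true(all(diff(sc$mech$force_N[post]) <= 0))
  # plastic area of the pre-divergence record is zero
  sel <- which(pre)
  expect_equal(plastic_area(sc$mech$force_N[sel], sc$mech$disp_mm[sel], m),
               rep(0, length(sel)))
})

test_that("frame-time interpolation is exact at the mechanics knots", {
  p <- small_scenario_params()
  sc <- synth_video(p)
  sy <- sync_frames(sc$frames, sc$mech)
  idx <- match(round(sy$t_s, 9), round(sc$mech$time_s, 9))
  expect_false(any(is.na(idx)))
  expect_identical(sy$force_N, sc$mech$force_N[idx])
  expect_identical(sy$disp_mm, sc$mech$disp_mm[idx])
})

test_that("the forward-computed reference R-curve is finite and rising", {
  sc <- default_scenario_run()$sc
  ref <- sc$reference_rcurve
  expect_true(all(is.finite(ref$J_kJm2)))
  expect_true(all(diff(ref$J_kJm2) >= 0))
  expect_true(all(ref$a_mm < sc$params$geometry$W))
})

test_that("a zero-amplitude scenario is a static video", {
  p <- small_scenario_params(amplitude = 0, jitter_sd = 0, noise_sd = 0.02)
  sc <- synth_video(p)
  tr <- track_front(sc$frames, sync_frames(sc$frames, sc$mech),
                    p$notch_tip_px, sc$calibration, threshold = 0.3,
                    join_operator = "opening", roi = p$roi,
                    displacement_mode = "vertical")
  expect_true(all(tr$da_raw_mm == 0))
  expect_true(all(is.na(tr$front_row)))
})

test_that("parameter validation rejects inconsistent scenarios", {
  expect_error(small_scenario_params(amplitude = 0.01, noise_sd = 0.05),
               "exceed the noise")
  expect_error(small_scenario_params(crack_lag_mm = -1), "lag")
  expect_error(scenario_params(img_shape = c(64, 64)), "image too small")
})
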