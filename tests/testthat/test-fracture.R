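geom <- specimen_geometry(B = 0.9, W = 0.9, a0 = 0.35, S = 6.15, nu = 0.33)

test_that("the linear slope is recovered from clean and noisy records", {
  d <- seq(0, 0.1, length.out = 50)
  fit <- fit_linear_slope(100 * d, d)
  expect_equal(fit$m, 100)
  expect_equal(fit$r2, 1)
  set.seed(8)
  fitn <- fit_linear_slope(100 * d + stats::rnorm(50, 0, 0.1), d,
                           window_fractions = c(0.1, 0.9))
  expect_lt(abs(fitn$m / 100 - 1), 0.02)
  expect_error(fit_linear_slope(rep(0, 10), d[1:10]), "no positive force")
})

test_that("the post-peak softening branch does not contaminate the fit", {
  t <- seq(0, 10, by = 0.05)
  d <- 0.01 * t
  F_ <- ifelse(t <= 5, 30 * d, 30 * 0.05 * exp(-(t - 5)))
  fit <- fit_linear_slope(F_, d)
  expect_equal(fit$m, 30, tolerance = 1e-10)
})

test_that("flexural modulus reduces to the un-notched beam relation at a0 = 0", {
  g0 <- specimen_geometry(0.9, 0.9, 0, 6.15)
  m <- 4 * 12000 * 0.9 * 0.9^3 / 6.15^3  # slope of a 12 GPa un-notched beam
  expect_equal(flexural_modulus(m, g0), 12000)
  expect_equal(flexural_modulus(135.4, g0), 12000, tolerance = 1e-4)
  expect_equal(flexural_modulus(2 * m, g0), 24000)  # linear in m
  # notched: the in-plane width is reduced by a0
  expect_equal(flexural_modulus(m, geom),
               6.15^3 * m / (4 * 0.9 * (0.9 - 0.35)^3))
})

test_that("the SE(B) geometry polynomial matches an independent transcription", {
  x <- seq(0.1, 0.9, by = 0.01)
  expect_equal(seb_geometry_factor(x), seb_f_reference(x), tolerance = 1e-10)
  expect_error(seb_geometry_factor(1), "a/W")
})

test_that("stress intensity is linear in force and unit-consistent", {
  expect_equal(stress_intensity(0, geom, 0.45), 0)
  K1 <- stress_intensity(3, geom, 0.45)
  expect_equal(stress_intensity(6, geom, 0.45), 2 * K1)
  # explicit unit bookkeeping: N, mm -> MPa sqrt(m)
  K_nmm <- 3 * 6.15 / (0.9 * 0.9^1.5) * seb_f_reference(0.5)
  expect_equal(K1, K_nmm * sqrt(1e-3), tolerance = 1e-12)
  expect_error(stress_intensity(1, geom, 0.9), "a/W")
})

test_that("plastic area vanishes for a linear record and matches the polygon oracle", {
  d <- seq(0, 0.2, length.out = 40)
  expect_equal(plastic_area(50 * d, d, 50), rep(0, 40))
  # ramp to (0.1, 5 N) then plateau at 5 N to 0.3 mm
  d2 <- c(seq(0, 0.1, length.out = 11), seq(0.12, 0.3, length.out = 10))
  F2 <- c(seq(0, 5, length.out = 11), rep(5, 10))
  m <- 50
  A <- plastic_area(F2, d2, m)
  dpl <- d2 - F2 / m
  # the F vs d_pl trace plus the return to zero force closes a polygon
  poly_x <- c(dpl, dpl[length(dpl)]); poly_y <- c(F2, 0)
  expect_equal(A[length(A)], shoelace_area(poly_x, poly_y))
  expect_true(all(diff(A) >= 0))
})

test_that("J decomposes exactly and the elastic-only state round-trips through K_eff", {
  a <- 0.45
  jp <- j_point(4, 0, geom, a, E = 12000)
  K <- stress_intensity(4, geom, a)
  expect_equal(jp$J_pl, 0)
  expect_equal(jp$J, jp$J_el)
  expect_equal(jp$J_el, K^2 * (1 - 0.33^2) / 12000 * 1000, tolerance = 1e-12)
  expect_equal(k_eff(jp$J, 12000, 0.33), K, tolerance = 1e-12)
  # plane-strain factor with nu = 0.33
  expect_equal(1 - geom$nu^2, 0.8911)
  # J_pl is linear in the plastic area
  j1 <- j_point(4, 0.02, geom, a, 12000)
  j2 <- j_point(4, 0.04, geom, a, 12000)
  expect_equal(j2$J_pl, 2 * j1$J_pl)
  # eta A / (B b0) in consistent units
  expect_equal(j1$J_pl, 1.9 * 0.02 / (0.9 * (0.9 - 0.35)))
  expect_error(j_point(4, 0, geom, 1.5, 12000), "a/W")
})

test_that("k_eff applies the plane-strain conversion on the stated scale", {
  expect_equal(k_eff(0, 12000, 0.33), 0)
  expect_equal(k_eff(1, 12000, 0.33), sqrt(1e-3 * 12000 / 0.8911))
  expect_equal(k_eff(1, 12000, 0.33, plane = "stress"), sqrt(1e-3 * 12000))
})

test_that("R-curve assembly truncates a >= W and keeps the decomposition", {
  tr <- data.frame(frame_idx = 0:9, t_s = 0:9, force_N = seq(0.5, 5, by = 0.5),
                   disp_mm = seq(0.5, 5, by = 0.5) / 30,
                   da_raw_mm = seq(0, 0.9, by = 0.1),
                   da_mono_mm = seq(0, 0.9, by = 0.1), synced = TRUE)
  expect_warning(rc <- build_rcurve(tr, geom, E = 12000, m = 30), "truncating")
  expect_true(all(rc$a_mm < geom$W))
  expect_equal(rc$J_kJm2, rc$Jel_kJm2 + rc$Jpl_kJm2)
  expect_true(all(rc$Jel_kJm2 >= 0) && all(rc$Jpl_kJm2 >= 0))
})

test_that("an empty or static trajectory yields a loading-line curve", {
  empty <- data.frame(frame_idx = integer(), t_s = numeric(),
                      force_N = numeric(), disp_mm = numeric(),
                      da_raw_mm = numeric(), da_mono_mm = numeric(),
                      synced = logical())
  expect_equal(nrow(build_rcurve(empty, geom, 12000)), 0)
  d <- seq(0, 0.1, length.out = 20)
  static <- data.frame(frame_idx = 0:19, t_s = d * 100, force_N = 30 * d,
                       disp_mm = d, da_raw_mm = 0, da_mono_mm = 0,
                       synced = TRUE)
  rc <- build_rcurve(static, geom, 12000, m = 30)
  expect_true(all(rc$da_mm == 0))
  expect_equal(rc$Jpl_kJm2, rep(0, nrow(rc)))
  expect_equal(rc$Keff_MPa_sqrt_m, rc$K_MPa_sqrt_m, tolerance = 1e-12)
})
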