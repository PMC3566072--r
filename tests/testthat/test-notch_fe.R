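geom_fe <- specimen_geometry(B = 0.9, W = 0.9, a0 = 0.3, S = 6.15, nu = 0.33)

# stiffnesses at the four studied notch lengths are reused across tests
fe_slopes <- local({
  a0s <- c(0, 0.075, 0.15, 0.3)
  list(a0 = a0s,
       m = vapply(a0s, function(a0)
         solve_bend(mesh_beam(geom_fe, a0), 12000, 0.33)$m, 0))
})

test_that("the mesh is a structured grid with a traction-free slot", {
  m0 <- mesh_beam(geom_fe, 0)
  expect_equal(nrow(m0$nodes), length(m0$xg) * length(m0$yg))
  expect_equal(m0$n_elements, (length(m0$xg) - 1) * (length(m0$yg) - 1))
  expect_gt(m0$n_elements, 300)   # order 10^3 at the default sizes
  expect_lt(m0$n_elements, 10000)
  m3 <- mesh_beam(geom_fe, 0.3)
  # the slot duplicates exactly the midspan nodes below the tip
  n_split <- sum(m3$yg < 0.3 - 1e-9)
  expect_equal(nrow(m3$nodes), length(m3$xg) * length(m3$yg) + n_split)
  # slot depth spans one third of the section
  expect_equal(max(m3$yg[m3$yg < 0.3 + 1e-9]), 0.3)
  expect_error(mesh_beam(geom_fe, 0.95), "a0")
  expect_error(mesh_beam(geom_fe, 0, elem_size_fine = 2), "element size")
})

test_that("the un-notched solve approaches Euler-Bernoulli for a slender beam", {
  g <- specimen_geometry(B = 0.9, W = 0.9, a0 = 0, S = 13.5, nu = 0.33)
  sol <- solve_bend(mesh_beam(g, 0, elem_size_fine = 0.05,
                              elem_size_coarse = 0.1), 12000, 0.33)
  m_eb <- 48 * 12000 * (0.9 * 0.9^3 / 12) / 13.5^3
  expect_lt(abs(sol$m / m_eb - 1), 0.03)
})

test_that("the solution is linear in E and symmetric about midspan", {
  mesh <- mesh_beam(geom_fe, 0, elem_size_fine = 0.1, elem_size_coarse = 0.2)
  s1 <- solve_bend(mesh, 6000, 0.33)
  s2 <- solve_bend(mesh, 12000, 0.33)
  expect_equal(s2$m, 2 * s1$m, tolerance = 1e-10)
  r <- s2$support_reactions_N
  expect_lt(abs(r["left"] / r["right"] - 1), 1e-8)
})

test_that("stiffness decreases strictly with notch length", {
  expect_true(all(diff(fe_slopes$m) < 0))
})

test_that("the mesh is converged: halving the element size moves m by < 1 %", {
  # smooth (un-notched) configuration; the slot tip itself carries a
  # stress singularity and converges more slowly by nature
  m_c <- solve_bend(mesh_beam(geom_fe, 0, elem_size_fine = 0.05,
                              elem_size_coarse = 0.15), 12000, 0.33)$m
  m_f <- solve_bend(mesh_beam(geom_fe, 0, elem_size_fine = 0.025,
                              elem_size_coarse = 0.1), 12000, 0.33)$m
  expect_lt(abs(m_c / m_f - 1), 0.01)
})

test_that("modulus calibration is one-step and independent of the trial value", {
  m_exp <- fe_slopes$m[4]
  expect_equal(calibrate_E(m_exp, geom_fe, 0.3), 12000, tolerance = 1e-9)
  E5 <- calibrate_E(m_exp, geom_fe, 0.3, E_trial = 5000)
  E20 <- calibrate_E(m_exp, geom_fe, 0.3, E_trial = 20000)
  expect_equal(E5, E20, tolerance = 1e-10)
  expect_equal(calibrate_E(2 * m_exp, geom_fe, 0.3), 2 * 12000,
               tolerance = 1e-9)
})

test_that("the second-order correction closes the loop at every fitted a0", {
  model <- fit_correction(fe_slopes$a0, fe_slopes$m, geom_fe)
  expect_equal(model$coeffs[1], 1)
  expect_gt(model$r2, 0.99)
  # the apparent-modulus ratio grows with notch length (the notched
  # flexural formula overestimates), and dividing it out recovers one
  # consistent un-notched modulus
  expect_true(all(diff(model$table$ratio) >= 0))
  E_rec <- vapply(seq_along(fe_slopes$a0), function(i) {
    g <- geom_fe; g$a0 <- fe_slopes$a0[i]
    correct_modulus(flexural_modulus(fe_slopes$m[i], g), fe_slopes$a0[i], model)
  }, 0)
  expect_true(all(abs(E_rec / E_rec[1] - 1) < 0.02))
  # a0 = 0: the correction is the identity
  expect_equal(correct_modulus(5000, 0, model), 5000)
  expect_warning(correct_modulus(5000, 0.5, model), "extrapolating")
  expect_warning(e <- correct_modulus(5000, 0.1, NULL), "no notch-correction")
  expect_equal(e, 5000)
})

test_that("slopes consistent with no notch effect give the identity model", {
  a0s <- c(0, 0.1, 0.2, 0.3)
  Ef0 <- 12000
  m_flat <- 4 * Ef0 * geom_fe$B * (geom_fe$W - a0s)^3 / geom_fe$S^3
  model <- fit_correction(a0s, m_flat, geom_fe)
  expect_equal(predict_ratio <- model$coeffs[2:3], c(0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("correction fitting validates its inputs", {
  expect_error(fit_correction(c(0, 0.1), c(1, 2), geom_fe), "at least 3")
  expect_error(fit_correction(c(0.1, 0.2, 0.3), c(1, 2, 3), geom_fe),
               "include 0")
})

test_that("the correction model survives a JSON round trip", {
  model <- fit_correction(fe_slopes$a0, fe_slopes$m, geom_fe)
  f <- withr::local_tempfile(fileext = ".json")
  write_correction_json(model, f)
  back <- read_correction_json(f)
  expect_equal(back$coeffs, model$coeffs)
  expect_equal(back$a0_range, model$a0_range)
  expect_equal(correct_modulus(15000, 0.2, back),
               correct_modulus(15000, 0.2, model))
})
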