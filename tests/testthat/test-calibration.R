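test_that("reduced CCS transform has the stated unit factors and inverse", {
  # mu = 1 when ion and gas masses are both 2 Da -> CCS' = CCS
  expect_equal(reduced_ccs(250, mz = 2, z = 1, m_gas_da = 2), 250)
  # doubling z at fixed CCS and mu halves CCS' (same ion mass, z doubled)
  c1 <- reduced_ccs(250, mz = 1000, z = 1)
  c2 <- reduced_ccs(250, mz = 500, z = 2)
  expect_equal(c2 / c1, 0.5, tolerance = 1e-12)
  for (ccs in c(150, 250, 440)) {
    expect_equal(reduced_ccs_inverse(reduced_ccs(ccs, 1222, 1), 1222, 1), ccs,
                 tolerance = 1e-12)
  }
  expect_error(reduced_ccs(250, 622, z = 0), "non-zero")
})

test_that("each model family recovers data generated from itself", {
  t <- c(200, 350, 500, 700, 900, 1100)
  mz <- seq(600, 2600, length.out = 6)
  # exact power law
  y_pow <- 30 * t^0.45
  ccs_ref <- reduced_ccs_inverse(y_pow, mz, 1)
  pts <- reference_points(paste0("p", 1:6), mz, 1, t, ccs_ref)
  m <- fit_calibration(pts, "power")
  expect_equal(unname(m$coefficients["a"]), 30, tolerance = 1e-6)
  expect_equal(unname(m$coefficients["b"]), 0.45, tolerance = 1e-6)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  # exact cubic: poly3 perfect, poly2 short
  y_cub <- 100 + 2 * t + 0.004 * t^2 - 1.5e-6 * t^3
  pts_c <- reference_points(paste0("c", 1:6), mz, 1, t,
                            reduced_ccs_inverse(y_cub, mz, 1))
  m3 <- fit_calibration(pts_c, "poly3")
  m2 <- fit_calibration(pts_c, "poly2")
  expect_equal(m3$r2, 1, tolerance = 1e-9)
  expect_lt(m2$r2, 1 - 1e-6)
  # nested-model property: poly3 residuals never exceed poly2's
  set.seed(5)
  y_noisy <- y_cub * (1 + rnorm(6, 0, 0.002))
  pts_n <- reference_points(paste0("n", 1:6), mz, 1, t,
                            reduced_ccs_inverse(y_noisy, mz, 1))
  rss <- function(model) {
    sum((slimsep:::.predict_reduced(model, t) - pts_n$ccs_reduced)^2)
  }
  expect_lte(rss(fit_calibration(pts_n, "poly3")),
             rss(fit_calibration(pts_n, "poly2")) + 1e-9)
})

test_that("calibration fitting validates its inputs", {
  t <- c(200, 350, 500, 700)
  pts <- reference_points(paste0("p", 1:4), seq(600, 1500, length.out = 4),
                          1, t, seq(200, 300, length.out = 4))
  expect_error(fit_calibration(pts, "poly3"), "at least 5")
  bad <- pts; bad$arrival_time_ms[2] <- bad$arrival_time_ms[1]
  expect_error(fit_calibration(bad, "poly2"), "strictly increasing")
  # non-monotone fitted curve inside the range raises a warning flag
  t6 <- seq(100, 600, by = 100)
  wig <- c(200, 380, 250, 480, 300, 560)
  pts_w <- suppressWarnings(
    reference_points(paste0("w", 1:6), seq(600, 2600, length.out = 6), 1, t6,
                     wig))
  expect_warning(mw <- fit_calibration(pts_w, "poly3"), "not monotone")
  expect_false(mw$monotone)
})

test_that("applying a perfect-fit model reproduces the training CCS", {
  t <- c(200, 350, 500, 700, 900, 1100)
  mz <- seq(600, 2600, length.out = 6)
  y <- 100 + 2 * t + 0.004 * t^2 - 1.5e-6 * t^3
  ccs_ref <- reduced_ccs_inverse(y, mz, 1)
  pts <- reference_points(paste0("p", 1:6), mz, 1, t, ccs_ref)
  m <- fit_calibration(pts, "poly3")
  expect_equal(apply_calibration(m, t, mz, 1), ccs_ref, tolerance = 1e-9)
  # extrapolation is rejected without an explicit override
  expect_error(apply_calibration(m, 1.2 * max(t), 2722, 1), "valid range")
  expect_silent(apply_calibration(m, 1.2 * max(t), 2722, 1,
                                  extrapolate = TRUE))
})

test_that("bias calculations are signed and order-invariant in aggregate", {
  expect_equal(ccs_bias(100.5, 100), 0.5)
  expect_equal(ccs_bias(99.88, 100), -0.12)
  expect_equal(ccs_bias(100, 100), 0)
  calc <- c(201, 248, 290, 330); ref <- c(200, 250, 289, 333)
  s1 <- ccs_bias_summary(calc, ref)
  ord <- c(3, 1, 4, 2)
  s2 <- ccs_bias_summary(calc[ord], ref[ord])
  expect_equal(s1$mean_abs_bias_pct, s2$mean_abs_bias_pct)
  expect_equal(s1$mean_bias_pct, s2$mean_bias_pct)
})

test_that("calibration models survive a JSON round trip", {
  t <- c(200, 350, 500, 700, 900, 1100)
  mz <- seq(600, 2600, length.out = 6)
  pts <- reference_points(paste0("p", 1:6), mz, 1, t, 30 * t^0.45 / sqrt(28) * 28)
  m <- fit_calibration(pts, "power", provenance = list(wave_speed_m_s = 180))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$kind, m$kind)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m2$valid_time_range, m$valid_time_range)
  expect_equal(
    apply_calibration(m2, 555, 1500, 1),
    apply_calibration(m, 555, 1500, 1), tolerance = 1e-12)
})
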