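small_grid <- function(seed = 1L) {
  benchmark_grid(wave_speeds_m_s = c(90, 180), amplitudes_vpp = 40,
                 waveforms = "sine", replicates = 2L, seed = seed)
}

test_that("grid bookkeeping: one record per ion x condition x replicate", {
  panel <- tune_mix_panel()[c(1, 5, 8)]
  res <- run_grid(panel, small_grid())
  expect_equal(nrow(res), 3 * 2 * 1 * 1 * 2)
  expect_setequal(unique(res$label), c("mz622", "mz1822", "mz2722"))
  # surfing records carry no resolving power
  expect_true(all(is.na(res$rp_ccs[res$regime == "surfing"])))
  expect_true(all(is.na(res$fwhm_ms[res$regime == "surfing"])))
})

test_that("grid results are byte-identical for a fixed master seed", {
  panel <- tune_mix_panel()[c(2, 6)]
  r1 <- run_grid(panel, small_grid(seed = 99))
  r2 <- run_grid(panel, small_grid(seed = 99))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_grid(panel, small_grid(seed = 100))
  expect_false(identical(r1$arrival_time_ms, r3$arrival_time_ms))
})

test_that("an all-surfing configuration yields no resolving-power records", {
  grid <- benchmark_grid(wave_speeds_m_s = 45, amplitudes_vpp = 40,
                         waveforms = "sine", replicates = 1L)
  res <- run_grid(tune_mix_panel(), grid)
  expect_equal(nrow(res), 8)
  expect_true(all(res$regime == "surfing"))
  expect_equal(sum(!is.na(res$rp_ccs)), 0)
})

test_that("region summaries bin arrival times and flag the best bin", {
  panel <- tune_mix_panel()[c(3, 5, 7)]
  res <- run_grid(panel, small_grid())
  s <- summarize_regions(res, bin_width_ms = 200)
  expect_false(attr(s, "empty"))
  expect_equal(sum(s$is_max_median), 1)
  expect_equal(sum(s$n), sum(!is.na(res$rp_ccs)))
  # one giant bin spans everything
  s1 <- summarize_regions(res, bin_width_ms = 1e6)
  expect_equal(nrow(s1), 1)
  # no mobility-selective records -> empty summary with flag
  surf_only <- res[res$regime == "surfing", ]
  s0 <- summarize_regions(surf_only)
  expect_true(attr(s0, "empty"))
  expect_equal(nrow(s0), 0)
})

test_that("isomer reports carry pair metrics and flag unresolved pairs", {
  # well-separated synthetic pair: baseline resolution expected
  tr <- make_two_gauss_trace(400, 420, 2, 2)
  rep1 <- isomer_report(list(tr), list(c(a = 203.5, b = 205.4)))
  expect_equal(nrow(rep1), 1)
  expect_true(rep1$separable)
  expect_equal(rep1$delta_ccs_pct, 100 * 1.9 / 203.5, tolerance = 1e-6)
  expect_gt(rep1$rpp, 2)
  expect_equal(rep1$valley_pct, 100, tolerance = 0.5)
  expect_gt(rep1$rp_ccs_spectrum, 0)
  # identical duplicate components: zero CCS difference -> not separable
  rep2 <- isomer_report(list(tr), list(c(x = 204, y = 204)))
  expect_false(rep2$separable)
  expect_equal(rep2$delta_ccs_pct, 0)
})

test_that("a configured 1% CCS pair at R_p 300 is resolved (R_pp > 1)", {
  # construct the trace from the metric definitions themselves:
  # fwhm_ccs = CCS / R_p, carried to time through a unit slope
  ccs <- c(300, 303); rp <- 300
  fwhm_t <- ccs / rp              # slope = 1 A^2/ms
  tr <- make_two_gauss_trace(ccs[1], ccs[2], fwhm_t[1], fwhm_t[2])
  rep <- isomer_report(list(tr), list(c(a = ccs[1], b = ccs[2])))
  expect_true(rep$separable)
  expect_gt(rep$rpp, 1)
  expect_equal(rep$rp_ccs_spectrum, 300, tolerance = 0.02)
})

test_that("model comparison ranks the generating family first", {
  t <- seq(200, 1200, length.out = 8)
  mz <- seq(600, 2700, length.out = 8)
  y_cub <- 100 + 2 * t + 0.004 * t^2 - 1.5e-6 * t^3
  set.seed(3)
  pts <- reference_points(paste0("p", 1:8), mz, 1, t,
                          reduced_ccs_inverse(y_cub * (1 + rnorm(8, 0, 1e-3)),
                                              mz, 1))
  cmp <- compare_calibrations(pts)
  expect_equal(cmp$kind[cmp$rank == 1], "poly3")
  expect_true(all(c("r2", "mean_abs_bias_pct") %in% names(cmp)))
  one <- compare_calibrations(pts, kinds = "power")
  expect_equal(nrow(one), 1)
})
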