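test_that("the local CCS-per-time slope behaves like a difference quotient", {
  expect_equal(ccs_per_time_slope(400, 450, 200, 210), 0.2)
  expect_equal(ccs_per_time_slope(450, 400, 210, 200), 0.2)  # symmetric
  # applying the slope to the pair's own spacing reproduces their dCCS
  sl <- ccs_per_time_slope(312.9, 406.9, 288.4, 323.8)
  expect_equal(sl * (406.9 - 312.9), 323.8 - 288.4, tolerance = 1e-12)
  expect_error(ccs_per_time_slope(400, 400, 200, 210), "coincident")
})

test_that("CCS resolving power follows the definition", {
  expect_equal(resolving_power_ccs(2, 0.1, 250), 1250)
  expect_equal(resolving_power_ccs(4, 0.1, 250), 625)   # doubling fwhm halves
  expect_equal(resolving_power_ccs(2, -0.1, 250), 1250) # sign-free
  expect_error(resolving_power_ccs(2, 0, 250), "non-zero")
  expect_error(resolving_power_ccs(0, 0.1, 250), "> 0")
  # spectrum-level convention uses mean CCS and mean width
  pk <- rbind(peak_row(400, 2), peak_row(450, 2))
  expect_equal(spectrum_resolving_power(pk, c(200, 210), 0.2),
               205 / (0.2 * 2))
})

test_that("two-peak resolution uses the Gaussian baseline-width convention", {
  w <- 2
  expect_equal(two_peak_resolution(peak_row(100, w), peak_row(100, w)), 0)
  expect_equal(two_peak_resolution(peak_row(100, w), peak_row(100 + 1.699 * w, w)), 1)
  expect_equal(two_peak_resolution(peak_row(100, w), peak_row(110, w)),
               two_peak_resolution(peak_row(110, w), peak_row(100, w)))
})

test_that("percent valley matches the analytic two-Gaussian oracle", {
  # frozen oracle values (closed-form evaluation of the Gaussian mixture)
  oracle <- c("1.5" = 97.7822, "1.1" = 82.2341, "1" = 72.9638, "0.8" = 44.7613)
  w <- 2
  for (rpp in names(oracle)) {
    sep <- as.numeric(rpp) * 1.699 * w
    v <- percent_valley(NULL, peak_row(100, w), peak_row(100 + sep, w))
    expect_equal(as.numeric(v), oracle[[rpp]], tolerance = 1e-3)
  }
  # far-separated peaks are baseline-resolved
  v100 <- percent_valley(NULL, peak_row(100, w), peak_row(140, w))
  expect_equal(as.numeric(v100), 100, tolerance = 1e-6)
  # merged feature: no interior minimum -> 0 with a flag
  v0 <- percent_valley(NULL, peak_row(100, w), peak_row(100.3, w))
  expect_equal(as.numeric(v0), 0)
  expect_true(attr(v0, "no_valley"))
  # trace-based evaluation agrees with the model-based one
  sep <- 1.1 * 1.699 * w
  tr <- make_two_gauss_trace(100, 100 + sep, w, w)
  p1 <- peak_row(100, w); p2 <- peak_row(100 + sep, w)
  expect_equal(as.numeric(percent_valley(tr, p1, p2)),
               as.numeric(percent_valley(NULL, p1, p2)), tolerance = 0.05)
})

test_that("percent valley grows monotonically with separation", {
  w <- 2
  seps <- seq(0.5, 6, by = 0.25) * w
  vals <- vapply(seps, function(s) {
    as.numeric(percent_valley(NULL, peak_row(100, w), peak_row(100 + s, w)))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("percent CCS difference uses the smaller value as denominator", {
  expect_equal(round(percent_ccs_difference(203.5, 205.4), 1), 0.9)
  expect_equal(percent_ccs_difference(205.4, 203.5),
               percent_ccs_difference(203.5, 205.4))
  expect_equal(percent_ccs_difference(200, 200), 0)
  expect_equal(percent_ccs_difference(200, 202), 1.0)
  expect_error(percent_ccs_difference(-1, 200), "> 0")
})
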