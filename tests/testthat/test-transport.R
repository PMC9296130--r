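# scale a species' CCS so its wave-speed ratio hits a target exactly
species_with_ratio <- function(target_c, config, mz = 1222) {
  base <- ion_species("probe", mz, 1, 300)
  c0 <- wave_speed_ratio(base, config)
  ion_species("probe", mz, 1, 300 * c0 / target_c)  # c scales as 1/CCS
}

test_that("mean ion speed follows the surfing / roll-over closed form", {
  cfg <- make_config(speed = 180, amp = 40)
  v <- cfg$wave$wave_speed_m_s
  # surfing limit: c >= 1 travels exactly at the wave speed
  surf <- species_with_ratio(1.3, cfg)
  expect_true(is_surfing(surf, cfg))
  expect_identical(mean_ion_speed(surf, cfg), v)
  # closed form at c = 0.6: 1 - sqrt(1 - 0.36) = 0.2
  p06 <- species_with_ratio(0.6, cfg)
  expect_equal(mean_ion_speed(p06, cfg), 0.2 * v, tolerance = 1e-10)
  # monotone increasing in c
  cs <- seq(0.05, 0.99, length.out = 20)
  speeds <- vapply(cs, function(ci) mean_ion_speed(species_with_ratio(ci, cfg), cfg),
                   numeric(1))
  expect_true(all(diff(speeds) > 0))
})

test_that("lower wave speeds push every ion toward surfing", {
  for (amp in c(30, 40)) {
    ratios <- sapply(c(225, 180, 135, 90, 45), function(vw) {
      cfg <- make_config(speed = vw, amp = amp)
      vapply(tune_mix_panel(), wave_speed_ratio, numeric(1), config = cfg)
    })
    # each row (ion) increases monotonically as speed decreases
    expect_true(all(apply(ratios, 1, function(r) all(diff(r) > 0))))
  }
})

test_that("square-wave drive carries a stronger fundamental field", {
  sq <- make_config(speed = 180, amp = 40, waveform = "square")
  si <- make_config(speed = 180, amp = 40, waveform = "sine")
  expect_equal(wave_field_max(sq) / wave_field_max(si), 4 / pi,
               tolerance = 1e-12)
})

test_that("arrival time is path over mean speed plus transit offset", {
  cfg <- make_config(speed = 225, amp = 40, t0 = 0)
  surf <- species_with_ratio(1.5, cfg)
  t <- arrival_time(surf, cfg)
  expect_equal(as.numeric(t), 13 / 225 * 1000, tolerance = 1e-9) # 57.8 ms
  expect_true(attr(t, "transmitted"))
  expect_true(attr(t, "surfing"))
  cfg5 <- make_config(speed = 225, amp = 40, t0 = 5)
  expect_equal(as.numeric(arrival_time(surf, cfg5)) - as.numeric(t), 5)
})

test_that("ion speed fraction inverts arrival times onto the wave speed", {
  cfg <- make_config(speed = 225, amp = 40, t0 = 0)
  t_surf <- 13 / 225 * 1000
  expect_equal(ion_speed_fraction(3 * t_surf, cfg), 100 / 3, tolerance = 1e-9)
  expect_equal(ion_speed_fraction(1.5 * t_surf, cfg), 200 / 3, tolerance = 1e-9)
  expect_equal(ion_speed_fraction(t_surf, cfg), 100, tolerance = 1e-9)
  expect_error(ion_speed_fraction(0, cfg), "exceed t0")
})

test_that("peak width reduces to the floor without diffusion and scales as sqrt(t)", {
  sp <- ion_species("x", 1522, 1, 324)
  cfg0 <- make_config(speed = 180, amp = 40, diffusion_scale = 0,
                      fwhm_floor_ms = 0.4, boundary_scale = 0)
  t <- as.numeric(arrival_time(sp, cfg0))
  expect_equal(peak_width(sp, t, cfg0), 0.4)
  # quadrupling the drift time at fixed mean speed doubles the diffusive fwhm:
  # same wave (same mean speed), 4x the path length, diffusion only
  mk <- function(L) sim_config(wave_config("sine", 40, wave_speed_m_s = 180),
                               transport_params(path_length_m = L, t0_ms = 0),
                               noise = "none", fwhm_floor_ms = 0,
                               boundary_scale = 0)
  c1 <- mk(13); c4 <- mk(52)
  t1 <- as.numeric(arrival_time(sp, c1)); t4 <- as.numeric(arrival_time(sp, c4))
  expect_equal(t4, 4 * t1, tolerance = 1e-12)
  expect_equal(peak_width(sp, t4, c4) / peak_width(sp, t1, c1), 2,
               tolerance = 1e-10)
})
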