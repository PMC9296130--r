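# Shared fixtures: all built in code, nothing read from disk.

# sine-drive config at the common assessment condition, noiseless by default
make_config <- function(speed = 180, amp = 40, waveform = "sine",
                        noise = "none", seed = 1L, t0 = 5, ...) {
  sim_config(wave_config(waveform, amp, wave_speed_m_s = speed),
             transport_params(t0_ms = t0),
             noise = noise, seed = seed, ...)
}

# a bare two-Gaussian trace with prescribed centroids/widths/heights
make_two_gauss_trace <- function(t1, t2, fwhm1, fwhm2, h1 = 1, h2 = 1,
                                 dt = 0.02, pad = 6) {
  s1 <- fwhm1 / 2.3548200450309493
  s2 <- fwhm2 / 2.3548200450309493
  tt <- seq(min(t1, t2) - pad * max(fwhm1, fwhm2),
            max(t1, t2) + pad * max(fwhm1, fwhm2), by = dt)
  y <- h1 * exp(-(tt - t1)^2 / (2 * s1^2)) + h2 * exp(-(tt - t2)^2 / (2 * s2^2))
  im_trace(tt, y)
}

# single-row peak descriptions for the analytic metric functions
peak_row <- function(t_p_ms, fwhm_ms, height = 1, baseline = 0) {
  tibble::tibble(t_p_ms = t_p_ms, fwhm_ms = fwhm_ms, height = height,
                 baseline = baseline)
}
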