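# Synthetic arrival-time trace generation.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate an arrival-time intensity trace for a panel of ions
#'
#' Each transmitted ion contributes a Gaussian peak centered at its
#' model arrival time with its diffusion-scaled fwhm; peaks are summed on a
#' regular time grid and detector noise is added according to the
#' configured noise model. Generation is bit-reproducible for a fixed
#' config seed.
#'
#' @param panel A list of [ion_species()] (or a single one).
#' @param config A [sim_config()].
#' @param window_ms Length-2 numeric sampling window in ms. `NULL` (default)
#'   auto-spans all peaks with a 10-fwhm margin. If a supplied window does
#'   not cover every peak, a warning string is recorded in the trace
#'   metadata (`$meta$warnings`).
#' @param heights Peak heights (recycled); default 1 for every ion.
#' @return An object of class `im_trace`: a list with `time_ms`,
#'   `intensity`, `peaks` (a tibble of the generating truth: label, mz, z,
#'   ccs_a2, t_ms, fwhm_ms, height, surfing, transmitted), and `meta`.
#' @examples
#' cfg <- sim_config(wave_config("sine", 40, wave_speed_m_s = 180),
#'                   noise = "none")
#' tr <- simulate_trace(tune_mix_panel(), cfg)
#' @export
simulate_trace <- function(panel, config, window_ms = NULL, heights = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(panel, "ion_species")) panel <- list(panel)
  if (!length(panel)) stop("`panel` must be non-empty")
  stopifnot(all(vapply(panel, inherits, logical(1), "ion_species")))
  heights <- rep_len(heights, length(panel))

  truth <- lapply(seq_along(panel), function(i) {
    sp <- panel[[i]]
    t_ms <- arrival_time(sp, config)
    transmitted <- attr(t_ms, "transmitted")
    surfing <- attr(t_ms, "surfing")
    fw <- if (transmitted) peak_width(sp, as.numeric(t_ms), config) else NA_real_
    tibble::tibble(label = sp$label, mz = sp$mz, z = sp$z, ccs_a2 = sp$ccs_a2,
                   t_ms = as.numeric(t_ms), fwhm_ms = fw, height = heights[i],
                   surfing = surfing, transmitted = transmitted)
  })
  truth <- dplyr::bind_rows(truth)

  warnings <- character()
  live <- truth[truth$transmitted, , drop = FALSE]
  if (!nrow(live)) stop("no transmitted ions in panel")
  if (is.null(window_ms)) {
    window_ms <- c(max(0, min(live$t_ms) - 10 * max(live$fwhm_ms)),
                   max(live$t_ms) + 10 * max(live$fwhm_ms))
  } else {
    stopifnot(length(window_ms) == 2, window_ms[2] > window_ms[1])
    if (any(live$t_ms < window_ms[1] | live$t_ms > window_ms[2])) {
      warnings <- c(warnings, "sampling window does not cover all peaks")
    }
  }
  dt <- config$sampling_interval_ms
  time_ms <- seq(window_ms[1], window_ms[2], by = dt)

  sig2 <- (live$fwhm_ms / .slim_const$fwhm_sigma)^2
  intensity <- rep(0, length(time_ms))
  for (i in seq_len(nrow(live))) {
    intensity <- intensity +
      live$height[i] * exp(-(time_ms - live$t_ms[i])^2 / (2 * sig2[i]))
  }

  if (config$noise != "none") {
    peak_max <- max(live$height)
    intensity <- with_seed(config$seed, {
      switch(config$noise,
        gaussian = intensity +
          stats::rnorm(length(intensity), 0, config$noise_scale * peak_max),
        shot = {
          counts_at_apex <- config$noise_scale
          stats::rpois(length(intensity),
                       pmax(intensity / peak_max, 0) * counts_at_apex) *
            peak_max / counts_at_apex
        })
    })
  }

  structure(
    list(time_ms = time_ms, intensity = intensity, peaks = truth,
         meta = list(
           waveform = config$wave$waveform,
           wave_speed_m_s = config$wave$wave_speed_m_s,
           amplitude_vpp = config$wave$amplitude_vpp,
           pressure_torr = config$transport$pressure_torr,
           temperature_k = config$transport$temperature_k,
           path_length_m = config$transport$path_length_m,
           t0_ms = config$transport$t0_ms,
           sampling_interval_ms = dt,
           noise = config$noise, noise_scale = config$noise_scale,
           seed = config$seed,
           warnings = warnings)),
    class = "im_trace"
  )
}

#' Construct an arrival-time trace from raw vectors
#'
#' Wraps externally supplied (e.g. file-read) time/intensity data in the
#' container the fitting and metric functions expect.
#'
#' @param time_ms Numeric vector of sample times in ms (strictly increasing).
#' @param intensity Numeric vector of intensities (same length).
#' @param meta Optional named list of acquisition metadata.
#' @return An `im_trace` object.
#' @export
im_trace <- function(time_ms, intensity, meta = list()) {
  stopifnot(is.numeric(time_ms), is.numeric(intensity),
            length(time_ms) == length(intensity), length(time_ms) >= 2)
  if (any(diff(time_ms) <= 0)) stop("`time_ms` must be strictly increasing")
  structure(list(time_ms = time_ms, intensity = intensity, peaks = NULL,
                 meta = meta),
            class = "im_trace")
}

#' @export
print.im_trace <- function(x, ...) {
  cat(sprintf("<im_trace> %d samples, %.1f-%.1f ms",
              length(x$time_ms), min(x$time_ms), max(x$time_ms)))
  if (!is.null(x$peaks)) cat(sprintf(", %d simulated peaks", nrow(x$peaks)))
  cat("\n")
  if (length(x$meta$warnings)) {
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}
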