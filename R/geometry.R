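#' Define a SLIM track geometry
#'
#' A SLIM separation track is a serpentine arrangement of ion-conveyor pad
#' electrodes. Consecutive pads repeat with a fixed pitch (pad length plus
#' inter-pad gap) and a fixed number of pads spans one full cycle of the
#' traveling waveform, so `pad_pitch_mm * pads_per_cycle` is the wavelength
#' of the drive.
#'
#' @param pad_pitch_mm Pad-to-pad distance in mm (pad length + gap).
#'   Default 1.125 mm (1.0 mm pad, 0.125 mm gap).
#' @param pads_per_cycle Number of conveyor pads spanning one waveform cycle
#'   (a "set"). Default 8.
#' @param path_length_m Total separation path length in m. Default 13.
#' @param board_gap_mm Spacing between the two mirrored electrode boards in
#'   mm; sets how strongly the surface waveform is attenuated at the ion's
#'   position midway between the boards. Default 3.
#'
#' @return An object of class `track_geometry`.
#' @examples
#' geo <- track_geometry()
#' wavelength(geo) # 9 mm
#' @export
track_geometry <- function(pad_pitch_mm = 1.125, pads_per_cycle = 8L,
                           path_length_m = 13, board_gap_mm = 3) {
  stopifnot(is.numeric(pad_pitch_mm), length(pad_pitch_mm) == 1,
            is.numeric(path_length_m), length(path_length_m) == 1)
  if (pad_pitch_mm <= 0) stop("`pad_pitch_mm` must be > 0")
  if (pads_per_cycle < 2 && pads_per_cycle != 1) {
    # a single-pad "cycle" is allowed as a degenerate identity case
    stop("`pads_per_cycle` must be >= 2 (or exactly 1 for the identity case)")
  }
  if (path_length_m <= 0) stop("`path_length_m` must be > 0")
  if (board_gap_mm <= 0) stop("`board_gap_mm` must be > 0")
  structure(
    list(pad_pitch_mm = pad_pitch_mm,
         pads_per_cycle = as.integer(pads_per_cycle),
         path_length_m = path_length_m,
         board_gap_mm = board_gap_mm),
    class = "track_geometry"
  )
}

#' @export
print.track_geometry <- function(x, ...) {
  cat("<track_geometry>\n")
  cat(sprintf("  pad pitch      : %.3f mm\n", x$pad_pitch_mm))
  cat(sprintf("  pads per cycle : %d\n", x$pads_per_cycle))
  cat(sprintf("  wavelength     : %.3f mm\n", wavelength(x)))
  cat(sprintf("  path length    : %g m (%d electrode sets)\n",
              x$path_length_m, electrode_sets(x)))
  invisible(x)
}

#' Traveling-wave wavelength of a track
#'
#' One waveform cycle is stepped across `pads_per_cycle` pads, so the
#' wavelength is the pad pitch times the number of pads per cycle
#' (1.125 mm x 8 = 9.0 mm for the default track).
#'
#' @param geometry A [track_geometry()].
#' @return Wavelength in mm.
#' @export
wavelength <- function(geometry) {
  stopifnot(inherits(geometry, "track_geometry"))
  geometry$pad_pitch_mm * geometry$pads_per_cycle
}

#' Convert switching frequency to wave speed (and back)
#'
#' The traveling wave advances one wavelength per switching cycle, so the
#' wave speed is `frequency x wavelength`. With the default 9.0 mm
#' wavelength, 5-25 kHz switching corresponds to 45-225 m/s.
#'
#' @param frequency_khz Waveform switching frequency in kHz (>= 0).
#' @param wave_speed_m_s Wave speed in m/s (>= 0).
#' @param geometry A [track_geometry()].
#' @return `wave_speed()`: speed in m/s. `wave_frequency()`: frequency in kHz.
#' @examples
#' wave_speed(5, track_geometry())  # 45 m/s
#' wave_frequency(225, track_geometry()) # 25 kHz
#' @export
wave_speed <- function(frequency_khz, geometry) {
  stopifnot(is.numeric(frequency_khz))
  if (any(frequency_khz < 0)) stop("`frequency_khz` must be >= 0")
  # kHz * mm = (1e3/s) * (1e-3 m) = m/s
  frequency_khz * wavelength(geometry)
}

#' @rdname wave_speed
#' @export
wave_frequency <- function(wave_speed_m_s, geometry) {
  stopifnot(is.numeric(wave_speed_m_s))
  if (any(wave_speed_m_s < 0)) stop("`wave_speed_m_s` must be >= 0")
  wave_speed_m_s / wavelength(geometry)
}

#' Count electrode sets (and conveyor pads) along a track
#'
#' An electrode "set" is one wavelength's worth of conveyor pads. Only
#' complete sets are counted (floor division); a partial set at the track
#' end is ignored. The default 13 m track with a 9.0 mm wavelength holds
#' 1444 sets.
#'
#' @param geometry A [track_geometry()].
#' @param n_rows Number of parallel conveyor-pad rows per board (the count
#'   of sets is per row). Default 5.
#' @return `electrode_sets()`: integer number of complete sets per row.
#'   `conveyor_pad_count()`: total number of conveyor pad electrodes across
#'   all rows.
#' @examples
#' electrode_sets(track_geometry())     # 1444
#' conveyor_pad_count(track_geometry()) # 57760, "nearly 60 000"
#' @export
electrode_sets <- function(geometry) {
  stopifnot(inherits(geometry, "track_geometry"))
  as.integer(floor(geometry$path_length_m * 1000 / wavelength(geometry)))
}

#' @rdname electrode_sets
#' @export
conveyor_pad_count <- function(geometry, n_rows = 5L) {
  stopifnot(n_rows >= 1)
  electrode_sets(geometry) * geometry$pads_per_cycle * as.integer(n_rows)
}

#' Define a traveling-wave drive configuration
#'
#' Either the switching frequency or the wave speed may be given; the other
#' is derived through the track wavelength. Adjacent pads within a set
#' receive the same waveform shifted by `360 / pads_per_cycle` degrees
#' (45 degrees for the default 8-pad set).
#'
#' @param waveform `"sine"` or `"square"`.
#' @param amplitude_vpp Peak-to-peak wave amplitude in V (30-40 V_pp is the
#'   surveyed operating range).
#' @param wave_speed_m_s Wave speed in m/s (default 180). At most one of
#'   `wave_speed_m_s` and `frequency_khz` may be supplied; the other is
#'   derived.
#' @param frequency_khz Switching frequency in kHz.
#' @param geometry A [track_geometry()].
#' @return An object of class `wave_config` carrying both the authoritative
#'   and the derived speed/frequency, the phase step, and the geometry.
#' @examples
#' wave_config("sine", 40, wave_speed_m_s = 180)
#' @export
wave_config <- function(waveform = c("sine", "square"), amplitude_vpp = 40,
                        wave_speed_m_s = 180, frequency_khz = NULL,
                        geometry = track_geometry()) {
  waveform <- match.arg(waveform)
  stopifnot(inherits(geometry, "track_geometry"))
  if (amplitude_vpp <= 0) stop("`amplitude_vpp` must be > 0")
  if (!missing(wave_speed_m_s) && !is.null(frequency_khz)) {
    stop("supply at most one of `wave_speed_m_s` or `frequency_khz`")
  }
  if (is.null(frequency_khz)) {
    authoritative <- "speed"
    frequency_khz <- wave_frequency(wave_speed_m_s, geometry)
  } else {
    authoritative <- "frequency"
    wave_speed_m_s <- wave_speed(frequency_khz, geometry)
  }
  structure(
    list(waveform = waveform,
         amplitude_vpp = amplitude_vpp,
         wave_speed_m_s = wave_speed_m_s,
         frequency_khz = frequency_khz,
         authoritative = authoritative,
         phase_step_deg = 360 / geometry$pads_per_cycle,
         geometry = geometry),
    class = "wave_config"
  )
}

#' @export
print.wave_config <- function(x, ...) {
  cat("<wave_config>\n")
  cat(sprintf("  %s wave, %.1f V_pp, %.1f m/s (%.3f kHz), %g deg phase step\n",
              x$waveform, x$amplitude_vpp, x$wave_speed_m_s, x$frequency_khz,
              x$phase_step_deg))
  invisible(x)
}

#' Instantaneous potentials on the electrodes of one set
#'
#' Returns the potential applied to each of the `n_electrodes` pads of one
#' electrode set at time `time_ms`. For a sine drive, pad `i` carries
#' `(A/2) * sin(2 pi f t - i * phase_step)`. The square drive is a stepped
#' two-level realization: at each of the `pads_per_cycle` switching steps
#' per cycle, half the pads sit at `+A/2` and half at `-A/2`, and the
#' high/low block advances one pad per step (the digital approximation of a
#' longitudinally propagating wave).
#'
#' @param config A [wave_config()].
#' @param time_ms Time in ms (may be a vector).
#' @param n_electrodes Number of electrodes in the set; must equal
#'   `pads_per_cycle` of the configured geometry.
#' @return A matrix with `length(time_ms)` rows and `n_electrodes` columns of
#'   potentials in V.
#' @examples
#' v <- waveform_potentials(wave_config("sine", 40, frequency_khz = 10), 0.025)
#' max(v) - min(v) # approaches 40 V over a full cycle
#' @export
waveform_potentials <- function(config, time_ms, n_electrodes = NULL) {
  stopifnot(inherits(config, "wave_config"))
  n_pads <- config$geometry$pads_per_cycle
  if (is.null(n_electrodes)) n_electrodes <- n_pads
  if (n_electrodes != n_pads) {
    stop("`n_electrodes` must equal `pads_per_cycle` (", n_pads, ")")
  }
  a2 <- config$amplitude_vpp / 2
  f <- config$frequency_khz              # kHz; time_ms * f = cycles
  i <- seq_len(n_pads) - 1
  phase <- i * config$phase_step_deg * pi / 180
  if (config$waveform == "sine") {
    out <- outer(2 * pi * f * time_ms, phase, function(th, ph) a2 * sin(th - ph))
  } else {
    # quantize time to the switching step (n_pads steps per cycle), then
    # take the sign of the underlying sinusoid: half the pads high, half low
    step <- 1 / (f * n_pads)             # ms per switching step
    tq <- floor(time_ms / step) * step
    out <- outer(2 * pi * f * tq, phase, function(th, ph) {
      s <- sin(th - ph + 1e-9)           # nudge breaks exact-zero ties high
      a2 * ifelse(s >= 0, 1, -1)
    })
  }
  dimnames(out) <- list(NULL, paste0("pad", i))
  out
}
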