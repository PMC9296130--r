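# Desk-scale benchmarking: resolving-power grids, region summaries,
# isomer-separation reports, calibration-model comparison.

#' Define a benchmarking grid
#'
#' The default grid matches the benchmarked operating space: five wave
#' speeds (45-225 m/s), three amplitudes (30-40 V_pp), square and sine
#' drives, three replicates, giving 8 ions x 5 x 3 x 2 x 3 = 720 records
#' for the tune-mix panel.
#'
#' @param wave_speeds_m_s Wave speeds in m/s.
#' @param amplitudes_vpp Wave amplitudes in V_pp.
#' @param waveforms Waveforms to survey (`"square"`, `"sine"`).
#' @param replicates Replicates per condition (>= 1).
#' @param seed Master seed; every replicate's generator seed derives from it
#'   deterministically.
#' @return An object of class `benchmark_grid`.
#' @export
benchmark_grid <- function(wave_speeds_m_s = c(45, 90, 135, 180, 225),
                           amplitudes_vpp = c(30, 35, 40),
                           waveforms = c("square", "sine"),
                           replicates = 3L, seed = 1L) {
  stopifnot(length(wave_speeds_m_s) >= 1, length(amplitudes_vpp) >= 1,
            length(waveforms) >= 1, replicates >= 1)
  waveforms <- match.arg(waveforms, c("square", "sine"), several.ok = TRUE)
  structure(
    list(wave_speeds_m_s = wave_speeds_m_s, amplitudes_vpp = amplitudes_vpp,
         waveforms = waveforms, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "benchmark_grid"
  )
}

#' @keywords internal
#' @noRd
.derive_seed <- function(master, cond_index, replicate) {
  # deterministic per-replicate fan-out, kept inside 32-bit integer range
  as.integer((as.numeric(master) + 104729 * cond_index + 7919 * replicate) %%
               2147483647L)
}

#' Run a resolving-power benchmark over a condition grid
#'
#' For every (wave speed, amplitude, waveform, replicate) cell the full
#' panel is simulated as one trace, each mobility-selective ion's peak is
#' fitted in a window around its predicted arrival time, and the CCS-based
#' resolving power is computed with the local slope taken between the ion
#' and its nearest-neighbor panel ion (next-highest m/z where available).
#' Surfing ions are transmitted but carry no resolving power (regime
#' `"surfing"`); fit failures are recorded per cell (`fit_ok = FALSE`) and
#' never abort the grid. The result is byte-identical for a fixed master
#' seed.
#'
#' @param panel List of [ion_species()] (default [tune_mix_panel()]).
#' @param grid A [benchmark_grid()].
#' @param transport A [transport_params()].
#' @param sampling_interval_ms Trace sampling interval, ms.
#' @param noise,noise_scale Noise model passed to [sim_config()].
#' @return A long tibble with one record per ion x condition x replicate:
#'   `label, mz, wave_speed_m_s, amplitude_vpp, waveform, replicate,
#'   arrival_time_ms, fwhm_ms, rp_ccs, regime, fit_ok`.
#' @export
run_grid <- function(panel = tune_mix_panel(), grid = benchmark_grid(),
                     transport = transport_params(),
                     sampling_interval_ms = 0.05,
                     noise = "gaussian", noise_scale = 0.01) {
  stopifnot(inherits(grid, "benchmark_grid"))
  conds <- expand.grid(wave_speed_m_s = grid$wave_speeds_m_s,
                       amplitude_vpp = grid$amplitudes_vpp,
                       waveform = grid$waveforms,
                       stringsAsFactors = FALSE)
  ccs_panel <- vapply(panel, function(p) p$ccs_a2, numeric(1))
  out <- vector("list", nrow(conds) * grid$replicates)
  idx <- 0L
  for (ci in seq_len(nrow(conds))) {
    wv <- wave_config(conds$waveform[ci], conds$amplitude_vpp[ci],
                      wave_speed_m_s = conds$wave_speed_m_s[ci])
    for (rep_i in seq_len(grid$replicates)) {
      idx <- idx + 1L
      cfg <- sim_config(wv, transport,
                        sampling_interval_ms = sampling_interval_ms,
                        noise = noise, noise_scale = noise_scale,
                        seed = .derive_seed(grid$seed, ci, rep_i))
      out[[idx]] <- .run_grid_cell(panel, ccs_panel, cfg, conds[ci, ], rep_i)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "grid") <- grid
  res
}

#' @keywords internal
#' @noRd
.run_grid_cell <- function(panel, ccs_panel, cfg, cond, rep_i) {
  n <- length(panel)
  surf <- vapply(panel, is_surfing, logical(1), config = cfg)
  t_pred <- vapply(panel, function(p) as.numeric(arrival_time(p, cfg)), numeric(1))
  fw_pred <- vapply(seq_len(n), function(i) {
    peak_width(panel[[i]], t_pred[i], cfg)
  }, numeric(1))

  trace <- simulate_trace(panel, cfg)

  # fit only mobility-selective ions, each in a window around its predicted peak
  fits <- vector("list", n)
  for (i in which(!surf)) {
    w <- max(4 * fw_pred[i], 2)
    fits[[i]] <- fit_peaks(trace, initial_windows = list(c(t_pred[i] - w,
                                                           t_pred[i] + w)))
  }

  rows <- lapply(seq_len(n), function(i) {
    base <- tibble::tibble(
      label = panel[[i]]$label, mz = panel[[i]]$mz,
      wave_speed_m_s = cond$wave_speed_m_s,
      amplitude_vpp = cond$amplitude_vpp, waveform = cond$waveform,
      replicate = rep_i)
    if (surf[i]) {
      return(dplyr::mutate(base, arrival_time_ms = t_pred[i],
                           fwhm_ms = NA_real_, rp_ccs = NA_real_,
                           regime = "surfing", fit_ok = NA))
    }
    ft <- fits[[i]]
    ok <- isTRUE(ft$converged[1])
    # nearest-neighbor slope partner: next-highest m/z if selective, else
    # next-lowest (matching the convention of pairing with the adjacent ion)
    partner <- NA_integer_
    if (i < n && !surf[i + 1]) partner <- i + 1L
    else if (i > 1 && !surf[i - 1]) partner <- i - 1L
    rp <- NA_real_
    if (ok && !is.na(partner)) {
      pt <- if (!is.null(fits[[partner]]) && isTRUE(fits[[partner]]$converged[1])) {
        fits[[partner]]$t_p_ms[1]
      } else {
        t_pred[partner]
      }
      sl <- tryCatch(
        ccs_per_time_slope(ft$t_p_ms[1], pt, ccs_panel[i], ccs_panel[partner]),
        error = function(e) NA_real_)
      if (is.finite(sl) && sl != 0) {
        rp <- resolving_power_ccs(ft$fwhm_ms[1], sl, ccs_panel[i])
      }
    }
    dplyr::mutate(base,
                  arrival_time_ms = if (ok) ft$t_p_ms[1] else t_pred[i],
                  fwhm_ms = if (ok) ft$fwhm_ms[1] else NA_real_,
                  rp_ccs = rp, regime = "drift", fit_ok = ok)
  })
  dplyr::bind_rows(rows)
}

#' Summarize a grid result by arrival-time region
#'
#' Bins the mobility-selective records by arrival time (default 200 ms
#' bins) and reports per-bin resolving-power quartiles, flagging the bin
#' with the maximum median. Three regions typically emerge: a fast
#' near-surfing region with little selectivity, an intermediate
#' high-resolution band, and a slow diffusion-degraded tail.
#'
#' @param result A grid result tibble from [run_grid()].
#' @param bin_width_ms Bin width in ms (default 200).
#' @return A tibble `bin_start_ms, bin_end_ms, n, rp_median, rp_q1, rp_q3,
#'   is_max_median`; attribute `empty = TRUE` flags a result with no
#'   mobility-selective records.
#' @export
summarize_regions <- function(result, bin_width_ms = 200) {
  stopifnot(is.data.frame(result), bin_width_ms > 0)
  dr <- result[!is.na(result$rp_ccs), , drop = FALSE]
  if (!nrow(dr)) {
    out <- tibble::tibble(bin_start_ms = numeric(), bin_end_ms = numeric(),
                          n = integer(), rp_median = numeric(),
                          rp_q1 = numeric(), rp_q3 = numeric(),
                          is_max_median = logical())
    attr(out, "empty") <- TRUE
    return(out)
  }
  bin <- floor(dr$arrival_time_ms / bin_width_ms)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, rp = dr$rp_ccs), bin),
    n = dplyr::n(),
    rp_median = stats::median(rp),
    rp_q1 = stats::quantile(rp, 0.25, names = FALSE),
    rp_q3 = stats::quantile(rp, 0.75, names = FALSE),
    .groups = "drop")
  out <- dplyr::mutate(out, bin_start_ms = bin * bin_width_ms,
                       bin_end_ms = (bin + 1) * bin_width_ms)
  out <- dplyr::arrange(out, bin_start_ms)
  out$is_max_median <- seq_len(nrow(out)) == which.max(out$rp_median)
  attr(out, "empty") <- FALSE
  out[, c("bin_start_ms", "bin_end_ms", "n", "rp_median", "rp_q1", "rp_q3",
          "is_max_median")]
}

#' Separation metrics for isomer traces
#'
#' Fits each trace to its expected number of peaks and reports, for each
#' adjacent peak pair, the percent CCS difference, the two-peak resolution,
#' and the percent valley, plus the spectrum-level CCS resolving power
#' (average-CCS convention). Peaks are matched to the supplied CCS values
#' in arrival order (ascending CCS is assumed to elute last-to-first
#' consistently, i.e. larger CCS arrives later).
#'
#' @param traces A list of `im_trace` objects (one per isomer spectrum).
#' @param known_ccs A list (parallel to `traces`) of numeric CCS vectors in
#'   A^2, sorted ascending; names become component labels.
#' @return A tibble with one row per adjacent pair per spectrum:
#'   `spectrum, pair, delta_ccs_pct, rpp, valley_pct, rp_ccs_spectrum,
#'   separable`.
#' @export
isomer_report <- function(traces, known_ccs) {
  if (inherits(traces, "im_trace")) traces <- list(traces)
  stopifnot(length(traces) == length(known_ccs))
  rows <- lapply(seq_along(traces), function(si) {
    tr <- traces[[si]]
    ccs_sorted <- sort(known_ccs[[si]])
    lab <- names(ccs_sorted)
    ccs <- unname(ccs_sorted)
    n <- length(ccs)
    stopifnot(n >= 2)
    fits <- fit_peaks(tr, n_peaks = n)
    fits <- fits[order(fits$t_p_ms), , drop = FALSE]
    if (is.null(lab)) lab <- paste0("p", seq_len(n))
    out <- lapply(seq_len(n - 1), function(k) {
      p1 <- fits[k, ]; p2 <- fits[k + 1, ]
      sep <- isTRUE(p1$converged) && isTRUE(p2$converged) &&
        abs(p2$t_p_ms - p1$t_p_ms) > 1e-6
      d_ccs <- percent_ccs_difference(ccs[k], ccs[k + 1])
      if (!sep || d_ccs == 0) {
        return(tibble::tibble(
          spectrum = si, pair = paste(lab[k], lab[k + 1], sep = "/"),
          delta_ccs_pct = d_ccs, rpp = NA_real_, valley_pct = NA_real_,
          rp_ccs_spectrum = NA_real_, separable = FALSE))
      }
      sl <- ccs_per_time_slope(p1, p2, ccs[k], ccs[k + 1])
      tibble::tibble(
        spectrum = si, pair = paste(lab[k], lab[k + 1], sep = "/"),
        delta_ccs_pct = d_ccs,
        rpp = two_peak_resolution(p1, p2),
        valley_pct = as.numeric(percent_valley(tr, p1, p2)),
        rp_ccs_spectrum = spectrum_resolving_power(fits, ccs, sl),
        separable = TRUE)
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Compare calibration model families on one reference set
#'
#' Fits each requested model family to the same reference points and
#' reports the coefficient of determination and the mean absolute percent
#' bias at the (held-in) training points, ranked by bias.
#'
#' @param points A reference table from [reference_points()].
#' @param kinds Model families to compare.
#' @return A tibble `kind, r2, mean_abs_bias_pct, mean_bias_pct, rank`.
#' @export
compare_calibrations <- function(points,
                                 kinds = c("power", "poly2", "poly3")) {
  stopifnot(is.data.frame(points), nrow(points) >= 5)
  rows <- lapply(kinds, function(k) {
    model <- fit_calibration(points, k)
    calc <- apply_calibration(model, points$arrival_time_ms, points$mz,
                              points$z)
    s <- ccs_bias_summary(calc, points$ccs_ref_a2)
    tibble::tibble(kind = k, r2 = model$r2,
                   mean_abs_bias_pct = s$mean_abs_bias_pct,
                   mean_bias_pct = s$mean_bias_pct)
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- rank(out$mean_abs_bias_pct, ties.method = "first")
  dplyr::arrange(out, rank)
}
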