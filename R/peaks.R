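# Gaussian peak fitting of arrival-time traces.

#' @keywords internal
#' @noRd
.gauss <- function(t, h, c, s) h * exp(-(t - c)^2 / (2 * s^2))

# crude single-peak parameter guess around the tallest remaining feature
#' @keywords internal
#' @noRd
.guess_peak <- function(time_ms, y) {
  i <- which.max(y)
  h <- y[i]; c <- time_ms[i]
  half <- h / 2
  above <- y >= half
  # nearest half-max crossings around the apex
  left <- i; while (left > 1 && above[left - 1]) left <- left - 1
  right <- i; while (right < length(y) && above[right + 1]) right <- right + 1
  fwhm <- max(time_ms[right] - time_ms[left], 2 * median(diff(time_ms)))
  list(h = h, c = c, s = fwhm / .slim_const$fwhm_sigma)
}

#' Fit Gaussian peaks to an arrival-time trace
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt, [minpack.lm::nlsLM])
#' of `n_peaks` Gaussians plus a constant baseline. No smoothing is applied
#' before fitting. When `initial_windows` is given, each window is fitted
#' independently with a single Gaussian + baseline (fast and robust for
#' well-separated panels); otherwise all peaks are fitted jointly with
#' starting values obtained by iterative peak-pick-and-subtract.
#'
#' Fits that fail to converge are returned flagged (`converged = FALSE`)
#' with their starting values, never silently dropped. Requesting more
#' peaks than the trace resolves leaves the surplus components flagged the
#' same way (near-zero height or coincident centroids).
#'
#' @param trace An `im_trace` (see [simulate_trace()], [im_trace()]).
#' @param n_peaks Number of peaks to fit (ignored when `initial_windows`
#'   is supplied).
#' @param initial_windows Optional list (or 2-column matrix) of time windows
#'   `c(lo, hi)` in ms, one per expected peak.
#' @return A tibble of class `peak_fit` with one row per peak, sorted by
#'   centroid (ties broken by descending height): `peak`, `t_p_ms`,
#'   `fwhm_ms`, `height`, `baseline`, `fit_r2`, `converged`.
#' @examples
#' cfg <- sim_config(wave_config("sine", 40, wave_speed_m_s = 180),
#'                   noise = "none")
#' tr <- simulate_trace(tune_mix_panel()[[4]], cfg)
#' fit_peaks(tr, 1)
#' @export
fit_peaks <- function(trace, n_peaks = 1L, initial_windows = NULL) {
  stopifnot(inherits(trace, "im_trace"))
  if (!is.null(initial_windows)) {
    if (is.matrix(initial_windows)) {
      initial_windows <- split(initial_windows, row(initial_windows))
    }
    rows <- lapply(initial_windows, function(w) {
      sel <- trace$time_ms >= w[1] & trace$time_ms <= w[2]
      if (sum(sel) < 10) {
        return(.failed_fit_row(NA_real_, NA_real_, NA_real_))
      }
      .fit_gaussians(trace$time_ms[sel], trace$intensity[sel], 1L)
    })
    out <- dplyr::bind_rows(rows)
  } else {
    n_peaks <- as.integer(n_peaks)
    stopifnot(n_peaks >= 1)
    out <- .fit_gaussians(trace$time_ms, trace$intensity, n_peaks)
  }
  out <- out[order(out$t_p_ms, -out$height), , drop = FALSE]
  out$peak <- seq_len(nrow(out))
  class(out) <- c("peak_fit", class(out))
  out[, c("peak", "t_p_ms", "fwhm_ms", "height", "baseline", "fit_r2",
          "converged")]
}

#' @keywords internal
#' @noRd
.failed_fit_row <- function(c, s, h) {
  tibble::tibble(peak = NA_integer_, t_p_ms = c,
                 fwhm_ms = s * .slim_const$fwhm_sigma, height = h,
                 baseline = NA_real_, fit_r2 = NA_real_, converged = FALSE)
}

#' @keywords internal
#' @noRd
.fit_gaussians <- function(time_ms, y, n_peaks) {
  # iterative peak-pick-and-subtract starting values
  resid <- y - min(y)
  starts <- vector("list", n_peaks)
  for (k in seq_len(n_peaks)) {
    g <- .guess_peak(time_ms, resid)
    starts[[k]] <- g
    resid <- pmax(resid - .gauss(time_ms, g$h, g$c, g$s), 0)
  }
  start <- c(list(b0 = min(y)),
             stats::setNames(lapply(starts, `[[`, "h"), paste0("h", seq_len(n_peaks))),
             stats::setNames(lapply(starts, `[[`, "c"), paste0("c", seq_len(n_peaks))),
             stats::setNames(lapply(starts, `[[`, "s"), paste0("s", seq_len(n_peaks))))
  terms <- paste0("h", seq_len(n_peaks), " * exp(-(time_ms - c",
                  seq_len(n_peaks), ")^2 / (2 * s", seq_len(n_peaks), "^2))")
  fml <- stats::as.formula(paste("y ~ b0 +", paste(terms, collapse = " + ")))
  dat <- data.frame(time_ms = time_ms, y = y)
  dt_min <- min(diff(time_ms))
  lower <- c(-Inf, rep(0, n_peaks), rep(min(time_ms), n_peaks),
             rep(dt_min / 10, n_peaks))
  upper <- c(Inf, rep(Inf, n_peaks), rep(max(time_ms), n_peaks),
             rep(diff(range(time_ms)), n_peaks))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(dplyr::bind_rows(lapply(starts, function(g) {
      .failed_fit_row(g$c, g$s, g$h)
    })))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  conv <- isTRUE(fit$convInfo$isConv)
  h_max <- max(cf[grep("^h", names(cf))])
  rows <- lapply(seq_len(n_peaks), function(k) {
    h <- cf[[paste0("h", k)]]
    degenerate <- h <= h_max * 1e-6
    tibble::tibble(peak = k, t_p_ms = cf[[paste0("c", k)]],
                   fwhm_ms = abs(cf[[paste0("s", k)]]) * .slim_const$fwhm_sigma,
                   height = h, baseline = cf[["b0"]], fit_r2 = r2,
                   converged = conv && !degenerate)
  })
  dplyr::bind_rows(rows)
}
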