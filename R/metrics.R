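# Separation statistics: CCS-space resolving power, two-peak resolution,
# percent valley, percent CCS difference.

#' @keywords internal
#' @noRd
.peak_time <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p$t_p_ms
  } else {
    as.numeric(p)
  }
}

#' @keywords internal
#' @noRd
.peak_fwhm <- function(p) {
  stopifnot(is.data.frame(p), nrow(p) == 1)
  p$fwhm_ms
}

#' Local CCS-per-time slope from two calibration peaks
#'
#' `(CCS_p2 - CCS_p1) / (t_p2 - t_p1)`, the local linearization used to
#' carry peak widths from the time axis into CCS space. The global
#' arrival-time/CCS relationship is nonlinear, but across the width of a
#' single peak (and the spacing of neighboring calibrant peaks) the linear
#' approximation holds.
#'
#' @param p1,p2 Single-row `peak_fit` tibbles (or bare centroid times, ms).
#' @param ccs1,ccs2 The peaks' known CCS values in A^2.
#' @return Slope in A^2/ms (signed; symmetric under argument exchange).
#' @examples
#' ccs_per_time_slope(400, 450, 200, 210) # 0.2
#' @export
ccs_per_time_slope <- function(p1, p2, ccs1, ccs2) {
  t1 <- .peak_time(p1); t2 <- .peak_time(p2)
  if (isTRUE(all.equal(t1, t2))) stop("coincident centroids: slope undefined")
  (ccs2 - ccs1) / (t2 - t1)
}

#' CCS-based resolving power of a peak
#'
#' `R_p = CCS / (|slope| * fwhm)`: the peak's CCS divided by its fwhm
#' carried into CCS space through the local CCS-per-time slope.
#'
#' @param peak A single-row `peak_fit` tibble, or the fwhm in ms.
#' @param slope Local slope in A^2/ms (see [ccs_per_time_slope()]).
#' @param peak_ccs The peak's CCS in A^2.
#' @return Dimensionless resolving power (CCS/dCCS).
#' @examples
#' resolving_power_ccs(2, 0.1, 250) # 1250
#' @export
resolving_power_ccs <- function(peak, slope, peak_ccs) {
  fwhm <- if (is.data.frame(peak)) .peak_fwhm(peak) else as.numeric(peak)
  if (slope == 0) stop("`slope` must be non-zero")
  if (fwhm <= 0) stop("peak fwhm must be > 0")
  if (peak_ccs <= 0) stop("`peak_ccs` must be > 0")
  peak_ccs / (abs(slope) * fwhm)
}

#' Spectrum-level resolving power (average-CCS convention)
#'
#' For a spectrum containing multiple peaks, the resolving power is
#' reported using the mean of the peaks' CCS values and the mean of their
#' CCS-space widths.
#'
#' @param peaks A `peak_fit` tibble (>= 1 row).
#' @param ccs_a2 CCS of each peak, in the same row order.
#' @param slope Local slope in A^2/ms.
#' @return Dimensionless resolving power.
#' @export
spectrum_resolving_power <- function(peaks, ccs_a2, slope) {
  stopifnot(is.data.frame(peaks), nrow(peaks) == length(ccs_a2))
  if (slope == 0) stop("`slope` must be non-zero")
  mean(ccs_a2) / (abs(slope) * mean(peaks$fwhm_ms))
}

#' Two-peak resolution
#'
#' `R_pp = 2 |t_p2 - t_p1| / (width_factor * (fwhm1 + fwhm2))`. The default
#' `width_factor = 1.699` converts fwhm to the Gaussian baseline width
#' (width at 4 sigma), under which `R_pp = 1.5` coincides with ~100% valley
#' (baseline separation) for equal Gaussians. Symmetric in its arguments.
#'
#' @param p1,p2 Single-row `peak_fit` tibbles.
#' @param width_factor Baseline-width conversion factor on fwhm.
#' @return Dimensionless two-peak resolution (0 for coincident peaks).
#' @export
two_peak_resolution <- function(p1, p2, width_factor = 1.699) {
  dt <- abs(.peak_time(p2) - .peak_time(p1))
  2 * dt / (width_factor * (.peak_fwhm(p1) + .peak_fwhm(p2)))
}

#' Percent valley between two peaks
#'
#' `V = 100 * (1 - I_valley / I_lower_apex)`, clamped to [0, 100]: the depth
#' of the interior minimum between the two apexes relative to the LOWER
#' apex (conservative for unequal-abundance pairs). 100% means
#' baseline-resolved; a merged feature with no interior minimum gives 0%
#' (with attribute `no_valley = TRUE`).
#'
#' Given an `im_trace`, apexes and the interior minimum are read from the
#' sampled trace near the two fitted centroids. Given only two peak fits,
#' the fitted two-Gaussian model is evaluated on a fine grid.
#'
#' @param x An `im_trace`, or `NULL` to evaluate the fitted model only.
#' @param p1,p2 Single-row `peak_fit` tibbles.
#' @return Percent valley in [0, 100].
#' @examples
#' p1 <- tibble::tibble(t_p_ms = 100, fwhm_ms = 2, height = 1, baseline = 0)
#' p2 <- tibble::tibble(t_p_ms = 105.1, fwhm_ms = 2, height = 1, baseline = 0)
#' percent_valley(NULL, p1, p2) # ~97.8 (R_pp = 1.5)
#' @export
percent_valley <- function(x, p1, p2) {
  t1 <- .peak_time(p1); t2 <- .peak_time(p2)
  if (t1 > t2) { tmp <- p1; p1 <- p2; p2 <- tmp; tmp <- t1; t1 <- t2; t2 <- tmp }
  if (isTRUE(all.equal(t1, t2))) {
    return(structure(0, no_valley = TRUE))
  }
  if (inherits(x, "im_trace")) {
    time <- x$time_ms; y <- x$intensity
    base <- if (!is.null(p1$baseline) && is.finite(p1$baseline[1])) p1$baseline[1] else 0
    y <- y - base
  } else {
    w1 <- .peak_fwhm(p1) / .slim_const$fwhm_sigma
    w2 <- .peak_fwhm(p2) / .slim_const$fwhm_sigma
    time <- seq(t1 - 2 * .peak_fwhm(p1), t2 + 2 * .peak_fwhm(p2),
                length.out = 4096)
    y <- .gauss(time, p1$height, t1, w1) + .gauss(time, p2$height, t2, w2)
  }
  # observed apex positions: tallest sample within half a fwhm of each centroid
  in1 <- which(abs(time - t1) <= .peak_fwhm(p1) / 2)
  in2 <- which(abs(time - t2) <= .peak_fwhm(p2) / 2)
  if (!length(in1) || !length(in2)) return(structure(0, no_valley = TRUE))
  i1 <- in1[which.max(y[in1])]
  i2 <- in2[which.max(y[in2])]
  # merged feature: both searches land on the same apex (no interior minimum)
  if (i2 - i1 < 2) return(structure(0, no_valley = TRUE))
  a1 <- y[i1]; a2 <- y[i2]
  v_min <- min(y[(i1 + 1):(i2 - 1)])
  lower_apex <- min(a1, a2)
  if (lower_apex <= 0 || v_min >= lower_apex * (1 - 1e-12)) {
    return(structure(0, no_valley = TRUE))
  }
  max(0, min(100, 100 * (1 - v_min / lower_apex)))
}

#' Percent CCS difference between two values
#'
#' `100 * |ccs2 - ccs1| / min(ccs1, ccs2)`; the smaller CCS is the
#' denominator. The field reports this to one decimal place.
#'
#' @param ccs1,ccs2 CCS values in A^2 (> 0).
#' @return Percent difference (full precision; round for display).
#' @examples
#' round(percent_ccs_difference(203.5, 205.4), 1) # 0.9
#' @export
percent_ccs_difference <- function(ccs1, ccs2) {
  if (any(c(ccs1, ccs2) <= 0)) stop("CCS values must be > 0")
  100 * abs(ccs2 - ccs1) / pmin(ccs1, ccs2)
}
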