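# Reduced-CCS calibration: arrival time -> CCS via power / polynomial models.

#' Reduced CCS transform (and its inverse)
#'
#' `CCS' = CCS * sqrt(mu) / z`, where `mu` is the ion-neutral reduced mass
#' computed from the ion mass `mz * z` (electron and adduct masses folded
#' into the measured m/z) and the buffer gas mass. Folding the mass and
#' charge dependencies into the calibrated quantity lets a single
#' calibration curve span ions of differing mass and charge. Note this is
#' distinct from the transport-theory "reduced CCS" that removes
#' hard-sphere contributions.
#'
#' @param ccs_a2 CCS in A^2.
#' @param mz m/z in Th.
#' @param z Charge count (>= 1).
#' @param m_gas_da Buffer gas mass in Da (default N2).
#' @param ccs_reduced A reduced CCS value (for the inverse).
#' @return `reduced_ccs()`: CCS' in A^2 sqrt(Da). `reduced_ccs_inverse()`:
#'   CCS in A^2. The two round-trip exactly.
#' @examples
#' reduced_ccs_inverse(reduced_ccs(202, 622, 1), 622, 1) # 202
#' @export
reduced_ccs <- function(ccs_a2, mz, z = 1L, m_gas_da = 28.0134) {
  if (any(z == 0)) stop("`z` must be non-zero")
  if (any(ccs_a2 <= 0) || any(mz <= 0)) stop("inputs must be positive")
  mu <- reduced_mass(mz * z, m_gas_da)
  ccs_a2 * sqrt(mu) / z
}

#' @rdname reduced_ccs
#' @export
reduced_ccs_inverse <- function(ccs_reduced, mz, z = 1L, m_gas_da = 28.0134) {
  if (any(z == 0)) stop("`z` must be non-zero")
  mu <- reduced_mass(mz * z, m_gas_da)
  ccs_reduced * z / sqrt(mu)
}

#' Build a calibration reference table
#'
#' @param label Character vector of ion labels.
#' @param mz,z m/z (Th) and charge of each reference ion.
#' @param arrival_time_ms Measured arrival times in ms.
#' @param ccs_ref_a2 Reference (drift-tube) CCS values in A^2.
#' @param m_gas_da Buffer gas mass in Da.
#' @return A tibble with the inputs plus the derived `ccs_reduced` column,
#'   sorted by arrival time.
#' @export
reference_points <- function(label, mz, z, arrival_time_ms, ccs_ref_a2,
                             m_gas_da = 28.0134) {
  stopifnot(length(mz) == length(arrival_time_ms),
            length(mz) == length(ccs_ref_a2))
  if (any(arrival_time_ms <= 0) || any(ccs_ref_a2 <= 0) || any(mz <= 0)) {
    stop("all reference quantities must be positive")
  }
  out <- tibble::tibble(
    label = as.character(label), mz = mz, z = as.integer(z),
    arrival_time_ms = arrival_time_ms, ccs_ref_a2 = ccs_ref_a2,
    ccs_reduced = reduced_ccs(ccs_ref_a2, mz, z, m_gas_da))
  out <- out[order(out$arrival_time_ms), ]
  if (any(diff(out$ccs_reduced) <= 0)) {
    warning("reduced CCS is not strictly increasing with arrival time")
  }
  out
}

#' Fit a reduced-CCS calibration model
#'
#' Least-squares fit of reduced CCS versus arrival time with one of three
#' model families: `power` (`CCS' = a * t^b`, Levenberg-Marquardt with
#' log-log starting values), `poly2`, or `poly3` (raw-coefficient
#' polynomials via [stats::lm]). The fit is unweighted and no arrival-time
#' offset is subtracted. R^2 is computed on CCS'. Predictions are valid
#' inside `[min(t), max(t)]`; polynomial models in particular cannot be
#' extrapolated without large error.
#'
#' @param points A reference table from [reference_points()] (or any data
#'   frame with `arrival_time_ms`, `ccs_reduced`, and per-ion `mz`, `z`).
#' @param kind `"power"`, `"poly2"`, or `"poly3"`.
#' @param provenance Optional named list of acquisition metadata (wave
#'   speed, amplitude, ...) stored with the model.
#' @return An object of class `ccs_calibration`: kind, named coefficients,
#'   `valid_time_range`, `r2`, `monotone` flag, the training points, and
#'   provenance.
#' @examples
#' pts <- reference_points(letters[1:5], c(600, 900, 1200, 1500, 1800),
#'                         1, c(200, 350, 520, 700, 880),
#'                         c(200, 250, 295, 335, 370))
#' fit_calibration(pts, "poly3")
#' @export
fit_calibration <- function(points, kind = c("power", "poly2", "poly3"),
                            provenance = list()) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(points),
            all(c("arrival_time_ms", "ccs_reduced") %in% names(points)))
  points <- points[order(points$arrival_time_ms), , drop = FALSE]
  t <- points$arrival_time_ms
  y <- points$ccs_reduced
  if (any(diff(t) <= 0)) stop("arrival times must be strictly increasing")
  degree <- switch(kind, power = 1L, poly2 = 2L, poly3 = 3L)
  if (length(t) < degree + 2) {
    stop("need at least ", degree + 2, " points for a ", kind, " fit")
  }

  if (kind == "power") {
    ll <- stats::lm(log(y) ~ log(t))
    start <- list(a = exp(stats::coef(ll)[[1]]), b = stats::coef(ll)[[2]])
    fit <- minpack.lm::nlsLM(y ~ a * t^b, data = data.frame(t = t, y = y),
                             start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    coefs <- stats::coef(fit)
    predict_fun <- function(tt) coefs[["a"]] * tt^coefs[["b"]]
  } else {
    fml <- stats::as.formula(paste0("y ~ poly(t, ", degree, ", raw = TRUE)"))
    fit <- stats::lm(fml, data = data.frame(t = t, y = y))
    coefs <- stats::setNames(stats::coef(fit), paste0("c", 0:degree))
    predict_fun <- function(tt) {
      drop(outer(tt, 0:degree, `^`) %*% unname(coefs))
    }
  }
  fitted_y <- predict_fun(t)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- max(0, min(1, 1 - ss_res / ss_tot))

  grid <- seq(min(t), max(t), length.out = 256)
  monotone <- all(diff(predict_fun(grid)) > 0)
  if (!monotone) {
    warning("fitted calibration curve is not monotone inside its valid range")
  }

  structure(
    list(kind = kind, coefficients = coefs,
         valid_time_range = range(t), r2 = r2, monotone = monotone,
         points = points, provenance = provenance),
    class = "ccs_calibration"
  )
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("<ccs_calibration> %s fit, %d points, R^2 = %.5f\n",
              x$kind, nrow(x$points), x$r2))
  cat(sprintf("  valid arrival times: %.1f-%.1f ms%s\n",
              x$valid_time_range[1], x$valid_time_range[2],
              if (!x$monotone) " [non-monotone!]" else ""))
  cat("  coefficients:", paste(sprintf("%s = %.6g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
.predict_reduced <- function(model, t) {
  cf <- model$coefficients
  if (model$kind == "power") {
    cf[["a"]] * t^cf[["b"]]
  } else {
    degree <- length(cf) - 1
    drop(outer(t, 0:degree, `^`) %*% unname(cf))
  }
}

#' Apply a calibration model to arrival times
#'
#' Predicts the reduced CCS at each arrival time and inverts the reduced-CCS
#' transform for the queried ion's mass and charge. Times outside the
#' model's valid range are rejected unless `extrapolate = TRUE` is set
#' explicitly (polynomial calibrations extrapolate badly).
#'
#' @param model A `ccs_calibration` from [fit_calibration()].
#' @param arrival_time_ms Arrival time(s) in ms.
#' @param mz,z The ion's m/z and charge.
#' @param m_gas_da Buffer gas mass in Da.
#' @param extrapolate Allow predictions outside `valid_time_range`.
#' @return Calibrated CCS in A^2.
#' @export
apply_calibration <- function(model, arrival_time_ms, mz, z = 1L,
                              m_gas_da = 28.0134, extrapolate = FALSE) {
  stopifnot(inherits(model, "ccs_calibration"))
  rng <- model$valid_time_range
  tol <- 1e-9 * diff(rng)
  outside <- arrival_time_ms < rng[1] - tol | arrival_time_ms > rng[2] + tol
  if (any(outside) && !extrapolate) {
    stop("arrival time outside the calibration's valid range [",
         sprintf("%.1f, %.1f", rng[1], rng[2]),
         "] ms; set `extrapolate = TRUE` to override")
  }
  reduced_ccs_inverse(.predict_reduced(model, arrival_time_ms), mz, z, m_gas_da)
}

#' Percent CCS bias against a reference value
#'
#' `100 * (ccs_calc - ccs_ref) / ccs_ref`, signed: positive when the
#' calibrated value overshoots the reference.
#'
#' @param ccs_calc Calculated CCS in A^2.
#' @param ccs_ref Reference CCS in A^2 (> 0).
#' @return Signed percent bias (vectorized).
#' @examples
#' ccs_bias(100.5, 100) # 0.5
#' @export
ccs_bias <- function(ccs_calc, ccs_ref) {
  if (any(ccs_ref <= 0)) stop("`ccs_ref` must be > 0")
  100 * (ccs_calc - ccs_ref) / ccs_ref
}

#' Aggregate CCS bias across ions
#'
#' @inheritParams ccs_bias
#' @return A one-row tibble: `mean_bias_pct` (signed), `mean_abs_bias_pct`,
#'   `max_abs_bias_pct`, `n`.
#' @export
ccs_bias_summary <- function(ccs_calc, ccs_ref) {
  b <- ccs_bias(ccs_calc, ccs_ref)
  tibble::tibble(mean_bias_pct = mean(b), mean_abs_bias_pct = mean(abs(b)),
                 max_abs_bias_pct = max(abs(b)), n = length(b))
}
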