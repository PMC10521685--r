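#' Map an assembly trajectory to a turbidity curve
#'
#' Turbidity at 340 nm is modelled as linear in the fibrillar monomer
#' concentration (Rayleigh small-particle limit):
#' `OD(t) = baseline + alpha * B(t)`.
#'
#' @param traj An `assembly_trajectory` from [integrate_assembly()].
#' @param alpha OD units per mM of fibrillar monomer (>= 0).
#' @param baseline Instrument baseline OD.
#' @return A `kinetic_curve` tibble with columns `time_min`, `od340`.
#' @examples
#' traj <- integrate_assembly(bmpp_rates(1), mg_per_ml_to_mM(1), seq(0, 2000, 10))
#' observe_turbidity(traj, alpha = 10, baseline = 0.05)
#' @export
observe_turbidity <- function(traj, alpha, baseline = 0) {
  if (!is.numeric(alpha) || alpha < 0) {
    abort("`alpha` must be non-negative.", class = "fibrilkin_domain_error")
  }
  kinetic_curve(traj$time_min, baseline + alpha * traj$B_mM)
}

kinetic_curve <- function(time_min, od340, label = NULL) {
  out <- tibble::tibble(time_min = time_min, od340 = od340)
  structure(out, class = c("kinetic_curve", class(out)), label = label)
}

check_curve <- function(curve, min_len = 2L) {
  if (!all(c("time_min", "od340") %in% names(curve))) {
    abort("A kinetic curve needs columns `time_min` and `od340`.",
          class = "fibrilkin_domain_error")
  }
  if (nrow(curve) < min_len) {
    abort(sprintf("Curve too short: need at least %d samples.", min_len),
          class = "fibrilkin_domain_error")
  }
  if (any(diff(curve$time_min) <= 0) || any(!is.finite(curve$od340))) {
    abort("Curve times must be strictly increasing and values finite.",
          class = "fibrilkin_domain_error")
  }
  invisible(curve)
}

#' Savitzky-Golay-style smoothed derivative
#'
#' Local polynomial least-squares derivative on a uniform time grid. At each
#' sample the polynomial is fitted over a window of `window` points; near
#' the ends the window is shifted to stay inside the record (one-sided
#' fits), so the derivative is defined at every sample.
#'
#' @param curve A `kinetic_curve` (columns `time_min`, `od340`) on a
#'   uniform grid.
#' @param window Odd window length in samples, `polyorder < window <= n`.
#' @param polyorder Polynomial order (>= 1 for a derivative to exist).
#' @return A tibble `time_min`, `dod_dt` (OD/min).
#' @export
smooth_derivative <- function(curve, window = 7L, polyorder = 2L) {
  check_curve(curve, min_len = 2L)
  n <- nrow(curve)
  dt <- diff(curve$time_min)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    abort("Curve grid is non-uniform: resample to a uniform grid first.",
          class = "fibrilkin_domain_error")
  }
  if (window %% 2L != 1L || window <= polyorder || window > n || polyorder < 1L) {
    abort("Require odd `window`, polyorder >= 1, polyorder < window <= length(curve).",
          class = "fibrilkin_domain_error")
  }
  h <- (window - 1L) %/% 2L
  t <- curve$time_min; y <- curve$od340
  deriv <- vapply(seq_len(n), function(i) {
    lo <- min(max(1L, i - h), n - window + 1L)
    idx <- lo:(lo + window - 1L)
    x <- t[idx] - t[i]
    X <- outer(x, 0:polyorder, `^`)
    cf <- qr.coef(qr(X), y[idx])
    cf[2L]
  }, numeric(1))
  tibble::tibble(time_min = t, dod_dt = deriv)
}

# Plateau check shared by the descriptor and initializer stages: the OLS
# slope over the last decile must be indistinguishable from flat - below 1%
# of the peak slope, allowing 3 standard errors for observation noise.
check_saturated <- function(curve, dcurve) {
  n <- nrow(curve)
  tail_idx <- seq.int(min(max(1L, ceiling(0.9 * n)), n - 3L), n)
  v_max <- max(abs(dcurve$dod_dt))
  amp <- diff(range(curve$od340))
  fit <- lm(curve$od340[tail_idx] ~ curve$time_min[tail_idx])
  sl <- suppressWarnings(summary(fit)$coefficients)  # exact fits are fine here
  slope <- sl[2L, 1L]
  se <- if (is.finite(sl[2L, 2L])) sl[2L, 2L] else 0
  if (v_max <= 0 || amp <= 0 || abs(slope) > 0.01 * v_max + 3 * se) {
    abort("Curve not saturated: no plateau detectable in the last decile.",
          class = "fibrilkin_unsaturated_error")
  }
  invisible(TRUE)
}

#' Empirical descriptors of a sigmoidal kinetic curve
#'
#' Model-free summaries of an S-shaped (or saturating) aggregation record:
#' * `t50_min` - first time the signal crosses baseline + half amplitude
#'   (linear interpolation between samples);
#' * `v_max` - maximum of the smoothed derivative, OD/min;
#' * `lag_min` - tangent-intercept onset: the tangent at the point of
#'   maximum rate is extrapolated back to the baseline;
#' * `plateau` - mean of the last decile of the record;
#' * `baseline` - the initial signal level.
#'
#' @inheritParams smooth_derivative
#' @return A one-row tibble `lag_min`, `t50_min`, `v_max`, `plateau`,
#'   `baseline`, `amplitude`.
#' @export
sigmoid_descriptors <- function(curve, window = 7L, polyorder = 2L) {
  check_curve(curve, min_len = 10L)
  dcurve <- smooth_derivative(curve, window, polyorder)
  check_saturated(curve, dcurve)
  n <- nrow(curve)
  baseline <- mean(curve$od340[1:2])
  plateau <- mean(curve$od340[seq.int(max(1L, ceiling(0.9 * n)), n)])
  amp <- plateau - baseline
  half <- baseline + amp / 2
  above <- which(curve$od340 >= half)
  i2 <- above[above > 1L][1L]
  t50 <- if (is.na(i2)) NA_real_ else {
    i1 <- i2 - 1L
    curve$time_min[i1] + (half - curve$od340[i1]) /
      (curve$od340[i2] - curve$od340[i1]) *
      (curve$time_min[i2] - curve$time_min[i1])
  }
  i_v <- which.max(dcurve$dod_dt)
  v_max <- dcurve$dod_dt[i_v]
  lag <- curve$time_min[i_v] - (curve$od340[i_v] - baseline) / v_max
  tibble::tibble(lag_min = lag, t50_min = t50, v_max = v_max,
                 plateau = plateau, baseline = baseline, amplitude = amp)
}
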