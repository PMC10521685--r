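#' Synthetic coil and helix reference spectra
#'
#' Parametric Gaussian-band reference spectra for the two-state
#' coil-to-helix decomposition. The random-coil basis carries a single
#' strong negative band centred at 198 nm; the alpha-helix basis carries
#' the canonical negative bands at 208 and 222 nm and a positive band at
#' 193 nm. Amplitudes are in arbitrary ellipticity units (mdeg-like); only
#' ratios and mixing fractions are ever formed, so no path-length or
#' concentration normalization is applied.
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing; must
#'   cover at least 195-230 nm for downstream band reads.
#' @return A `cd_basis` tibble: `wavelength_nm`, `coil`, `helix`.
#' @examples
#' basis <- cd_reference_basis()
#' head(basis)
#' @export
cd_reference_basis <- function(wavelengths = seq(190, 250, by = 0.5)) {
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.",
          class = "fibrilkin_domain_error")
  }
  gauss <- function(w, centre, amp, width) amp * exp(-((w - centre) / width)^2 / 2)
  coil <- gauss(wavelengths, 198, -12, 10)
  helix <- gauss(wavelengths, 193, 6, 4) +
    gauss(wavelengths, 208, -11, 7.5) +
    gauss(wavelengths, 222, -10.5, 8)
  out <- tibble::tibble(wavelength_nm = wavelengths, coil = coil, helix = helix)
  structure(out, class = c("cd_basis", class(out)))
}

check_spectrum <- function(spec) {
  if (!all(c("wavelength_nm", "ellipticity") %in% names(spec))) {
    abort("A CD spectrum needs columns `wavelength_nm` and `ellipticity`.",
          class = "fibrilkin_domain_error")
  }
  if (any(diff(spec$wavelength_nm) <= 0) || any(!is.finite(spec$ellipticity))) {
    abort("Wavelengths must be strictly increasing and ellipticity finite.",
          class = "fibrilkin_domain_error")
  }
  invisible(spec)
}

band_read <- function(spec, centre, halfwidth = 2) {
  w <- spec$wavelength_nm
  if (min(w) > centre - halfwidth || max(w) < centre + halfwidth) {
    abort(sprintf("Spectrum does not cover the %g nm band (+/- %g nm).",
                  centre, halfwidth), class = "fibrilkin_domain_error")
  }
  grid <- seq(centre - halfwidth, centre + halfwidth, length.out = 41L)
  mean(approx(w, spec$ellipticity, grid)$y)
}

#' Helix-to-coil band intensity ratio
#'
#' The ratio `|theta(222)| / |theta(198)|`, with each band read as the mean
#' ellipticity over a +/- 2 nm window (linearly interpolated to the grid).
#' The ratio grows as the 198 nm random-coil band gives way to the 222 nm
#' alpha-helix band during assembly, and is invariant to uniform scaling of
#' the spectrum.
#'
#' @param spec A CD spectrum: tibble with `wavelength_nm`, `ellipticity`.
#' @param halfwidth Band read half-window, nm.
#' @return The dimensionless band ratio.
#' @export
band_ratio <- function(spec, halfwidth = 2) {
  check_spectrum(spec)
  t222 <- band_read(spec, 222, halfwidth)
  t198 <- band_read(spec, 198, halfwidth)
  if (abs(t198) < .Machine$double.eps) {
    abort("198 nm band is zero; ratio undefined.",
          class = "fibrilkin_domain_error")
  }
  abs(t222) / abs(t198)
}

#' Two-state coil/helix decomposition of a CD spectrum
#'
#' Least-squares solution of `spec ~ f * helix + (1 - f) * coil` over the
#' basis grid, with the helix fraction clipped to `[0, 1]`. Exact (to
#' machine precision) on any noiseless convex combination of the basis.
#'
#' @inheritParams band_ratio
#' @param basis A `cd_basis` from [cd_reference_basis()].
#' @return A one-row tibble: `f_helix`, `residual_norm`.
#' @export
decompose_two_state <- function(spec, basis) {
  check_spectrum(spec)
  d <- basis$helix - basis$coil
  denom <- sum(d^2)
  if (denom < 1e-10 * sum(basis$coil^2)) {
    abort("Degenerate basis: helix and coil spectra are indistinguishable.",
          class = "fibrilkin_conditioning_error")
  }
  y <- if (isTRUE(all.equal(spec$wavelength_nm, basis$wavelength_nm))) {
    spec$ellipticity
  } else {
    if (min(spec$wavelength_nm) > min(basis$wavelength_nm) ||
        max(spec$wavelength_nm) < max(basis$wavelength_nm)) {
      abort("Spectrum does not cover the basis grid; cannot interpolate.",
            class = "fibrilkin_domain_error")
    }
    approx(spec$wavelength_nm, spec$ellipticity, basis$wavelength_nm)$y
  }
  f <- sum((y - basis$coil) * d) / denom
  f <- min(max(f, 0), 1)
  res <- y - (f * basis$helix + (1 - f) * basis$coil)
  tibble::tibble(f_helix = f, residual_norm = sqrt(sum(res^2)))
}

#' Coil-to-helix transition kinetics from a CD time series
#'
#' Decomposes each spectrum of a timestamped series into a helix fraction
#' and fits the single-exponential relaxation
#' `f(t) = f_inf * (1 - exp(-k t)) + f_0 * exp(-k t)`.
#'
#' @param series A tibble with columns `time_min` and `spectrum`
#'   (list-column of CD spectra), as produced by [gen_cd_series()].
#' @param basis A `cd_basis`.
#' @return A `cd_transition` object: list with `fractions` (tibble
#'   `time_min`, `f_helix`), `rate_per_min`, `f0`, `f_inf`,
#'   `monotone` (FALSE flags non-monotone fractions beyond noise).
#' @export
transition_kinetics <- function(series, basis) {
  if (!all(c("time_min", "spectrum") %in% names(series)) || nrow(series) < 5L) {
    abort("`series` needs >= 5 rows with columns time_min and spectrum.",
          class = "fibrilkin_domain_error")
  }
  fr <- tibble::tibble(
    time_min = series$time_min,
    f_helix = purrr::map_dbl(series$spectrum,
                             ~ decompose_two_state(.x, basis)$f_helix)
  )
  f <- fr$f_helix; t <- fr$time_min
  span <- max(diff(range(f)), .Machine$double.eps)
  monotone <- all(diff(f) >= -0.05 * span)
  if (!monotone) {
    warn("Helix fraction is non-monotone beyond noise; fit returned anyway.",
         class = "fibrilkin_nonmonotone_warning")
  }
  obj <- function(p) {
    k <- exp(p[1L])
    fit <- p[3L] + (p[2L] - p[3L]) * exp(-k * t)
    sum((fit - f)^2)
  }
  # initial rate from the time to cover half the span
  t_half <- t[which(f >= f[1L] + span / 2)[1L]]
  k0 <- if (is.na(t_half) || t_half <= 0) 1 / max(t[t > 0], 1) else log(2) / t_half
  op <- optim(c(log(k0), f[1L], f[length(f)]), obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  structure(list(
    fractions = fr,
    rate_per_min = exp(op$par[1L]),
    f0 = op$par[2L], f_inf = op$par[3L],
    monotone = monotone,
    rate_identifiable = span > 1e-6,  # flat series leave k unconstrained
    objective = op$value
  ), class = "cd_transition")
}

#' @export
print.cd_transition <- function(x, ...) {
  cat(sprintf(
    "<cd_transition>  k = %.4g min^-1, f0 = %.3f -> f_inf = %.3f (%d points%s)\n",
    x$rate_per_min, x$f0, x$f_inf, nrow(x$fractions),
    if (x$monotone) "" else ", non-monotone"))
  invisible(x)
}
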