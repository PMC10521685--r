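# Shared fixtures, built in code at test time.

# one preset row as a convenient list
preset_row <- function(conc) {
  p <- bmpp_presets()
  as.list(p[p$conc_mg_ml == conc, ])
}

# noise-free turbidity round-trip input for a preset; t_max covers the
# full conversion (>= 10 half-times for each preset)
preset_curve <- function(conc, alpha = NULL, baseline = 0.05,
                         noise_sd = 0, seed = 1L) {
  p <- preset_row(conc)
  t_max <- c(`1` = 4500, `5` = 2400, `10` = 600)[[as.character(conc)]]
  if (is.null(alpha)) alpha <- 1.2 / p$A0_mM
  gen_turbidity(rate_constants(p$k1, p$k2, p$k3), p$A0_mM, alpha = alpha,
                baseline = baseline, t_max = t_max,
                noise_sd = noise_sd, seed = seed)
}

# symmetric logistic OD record with midpoint t0 and steepness s
logistic_curve <- function(t0 = 100, s = 10, lo = 0.05, hi = 1.05,
                           t_max = 400, dt = 2) {
  t <- seq(0, t_max, dt)
  fibrilkin:::kinetic_curve(t, lo + (hi - lo) / (1 + exp(-(t - t0) / s)))
}

basis_as_spectrum <- function(basis, which = c("coil", "helix"), scale = 1) {
  which <- match.arg(which)
  tibble::tibble(wavelength_nm = basis$wavelength_nm,
                 ellipticity = scale * basis[[which]])
}
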