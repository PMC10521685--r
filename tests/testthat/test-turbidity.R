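test_that("the observation model is linear in converted monomer", {
  tr <- integrate_assembly(bmpp_rates(1), 0.103, seq(0, 2000, 10))
  flat <- observe_turbidity(tr, alpha = 0, baseline = 0.07)
  expect_equal(flat$od340, rep(0.07, nrow(tr)))

  cv <- observe_turbidity(tr, alpha = 3, baseline = 0.05)
  expect_identical(cv$od340[1], 0.05)  # B(0) = 0
  cv2 <- observe_turbidity(tr, alpha = 6, baseline = 0.05)
  expect_equal(cv2$od340 - 0.05, 2 * (cv$od340 - 0.05))
  expect_error(observe_turbidity(tr, alpha = -1),
               class = "fibrilkin_domain_error")
})

test_that("the smoothed derivative is exact on polynomials and flags bad grids", {
  t <- seq(0, 100, 2)
  ramp <- fibrilkin:::kinetic_curve(t, 0.1 + 0.03 * t)
  d <- smooth_derivative(ramp, window = 7, polyorder = 2)
  expect_equal(d$dod_dt, rep(0.03, length(t)), tolerance = 1e-10)

  const <- fibrilkin:::kinetic_curve(t, rep(0.4, length(t)))
  expect_equal(smooth_derivative(const)$dod_dt, rep(0, length(t)),
               tolerance = 1e-12)

  # logistic: the derivative peaks at the midpoint
  lc <- logistic_curve(t0 = 100, s = 12, dt = 2)
  dl <- smooth_derivative(lc, window = 9, polyorder = 3)
  expect_lte(abs(dl$time_min[which.max(dl$dod_dt)] - 100), 2)

  bad <- fibrilkin:::kinetic_curve(c(0, 1, 3, 7, 20), 1:5)
  expect_error(smooth_derivative(bad), "resample",
               class = "fibrilkin_domain_error")
  expect_error(smooth_derivative(ramp, window = 6),
               class = "fibrilkin_domain_error")
  expect_error(smooth_derivative(ramp, window = 3, polyorder = 4),
               class = "fibrilkin_domain_error")
})

test_that("sigmoid descriptors recover the logistic midpoint and scale correctly", {
  lc <- logistic_curve(t0 = 120, s = 10, lo = 0.05, hi = 1.05,
                       t_max = 400, dt = 2)
  d <- sigmoid_descriptors(lc)
  expect_lte(abs(d$t50_min - 120), 2)          # within one sample of t0
  expect_equal(d$plateau, 1.05, tolerance = 1e-3)
  # the local-polynomial window flattens the peak slightly
  expect_equal(d$v_max, (1.05 - 0.05) / (4 * 10), tolerance = 0.05)

  # stretching the time axis by c scales lag and t50 by c, v_max by 1/c
  c_fac <- 3
  lc3 <- logistic_curve(t0 = 360, s = 30, lo = 0.05, hi = 1.05,
                        t_max = 1200, dt = 6)
  d3 <- sigmoid_descriptors(lc3)
  expect_equal(d3$t50_min, c_fac * d$t50_min, tolerance = 1e-3)
  expect_equal(d3$lag_min, c_fac * d$lag_min, tolerance = 0.02)
  expect_equal(d3$v_max, d$v_max / c_fac, tolerance = 1e-3)

  rising <- fibrilkin:::kinetic_curve(seq(0, 100, 5), exp(seq(0, 100, 5) / 30))
  expect_error(sigmoid_descriptors(rising),
               class = "fibrilkin_unsaturated_error")
})

test_that("assembly is faster at higher monomer concentration", {
  t50 <- vapply(c(1, 5, 10),
                function(conc) sigmoid_descriptors(preset_curve(conc))$t50_min,
                numeric(1))
  expect_lt(t50[3], t50[2])
  expect_lt(t50[2], t50[1])
})

test_that("t50 is stable under 1% observation noise", {
  p <- preset_row(10)
  r <- rate_constants(p$k1, p$k2, p$k3)
  clean_t50 <- sigmoid_descriptors(preset_curve(10))$t50_min
  shifts <- vapply(1:50, function(s) {
    cv <- gen_turbidity(r, p$A0_mM, alpha = 1.2 / p$A0_mM, baseline = 0.05,
                        t_max = 600, noise_sd = 0.012, seed = s)
    d <- try(sigmoid_descriptors(cv), silent = TRUE)
    if (inherits(d, "try-error")) return(NA_real_)
    abs(d$t50_min - clean_t50)
  }, numeric(1))
  expect_lt(median(shifts, na.rm = TRUE), 2 * 10)  # < 2 sampling intervals
})

test_that("derivative-based guesses land within a factor of 5 of truth", {
  for (conc in c(1, 5, 10)) {
    p <- preset_row(conc)
    alpha_true <- 1.2 / p$A0_mM
    g <- initial_guess(preset_curve(conc), p$A0_mM)
    ratios <- c(g$rates$k1 / p$k1, g$rates$k2 / p$k2, g$rates$k3 / p$k3,
                g$alpha / alpha_true)
    expect_true(all(ratios > 0.2 & ratios < 5))
  }
  flat <- fibrilkin:::kinetic_curve(seq(0, 500, 10), rep(0, 51))
  expect_error(initial_guess(flat, 0.1),
               class = "fibrilkin_unsaturated_error")
})

test_that("the initial slope of a generated curve is alpha * k1 * A0", {
  p <- preset_row(5)
  r <- rate_constants(p$k1, p$k2, p$k3)
  cv <- gen_turbidity(r, p$A0_mM, alpha = 2, baseline = 0.05,
                      t_max = 2400, sampling_interval = 1)
  d <- smooth_derivative(cv)
  expect_equal(d$dod_dt[1], 2 * p$k1 * p$A0_mM, tolerance = 0.05)
})

test_that("noise-free round-trip fitting recovers the generating constants", {
  p <- preset_row(10)
  cv <- preset_curve(10)
  fit <- fit_kinetics(cv, p$A0_mM, n_starts = 16, seed = 0)
  expect_true(fit$converged)
  expect_equal(fit$rates$k1, p$k1, tolerance = 0.01)
  expect_equal(fit$rates$k2, p$k2, tolerance = 0.01)
  expect_equal(fit$rates$k3, p$k3, tolerance = 0.01)
  expect_equal(fit$alpha, 1.2 / p$A0_mM, tolerance = 0.01)

  # fixed seed fixes the result
  fit2 <- fit_kinetics(cv, p$A0_mM, n_starts = 16, seed = 0)
  expect_identical(tidy(fit), tidy(fit2))

  # the optimizer never worsens the initializer
  g <- initial_guess(cv, p$A0_mM)
  tr <- integrate_assembly(g$rates, p$A0_mM, cv$time_min)
  resid0 <- sqrt(sum((g$baseline + g$alpha * tr$B_mM - cv$od340)^2))
  expect_lte(fit$residual_norm, resid0)
})

test_that("fitting tolerates 1% noise with bounded error on k1", {
  p <- preset_row(10)
  r <- rate_constants(p$k1, p$k2, p$k3)
  errs <- vapply(1:20, function(s) {
    cv <- gen_turbidity(r, p$A0_mM, alpha = 1.2 / p$A0_mM, baseline = 0.05,
                        t_max = 800, noise_sd = 0.012, seed = s)
    f <- try(fit_kinetics(cv, p$A0_mM, n_starts = 4, seed = 0), silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    abs(f$rates$k1 - p$k1) / p$k1
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("a flat record cannot be fitted and says so", {
  flat <- fibrilkin:::kinetic_curve(seq(0, 500, 10),
                                    rep(0.05, 51))
  expect_error(fit_kinetics(flat, 0.1, n_starts = 2, seed = 0),
               class = "fibrilkin_nonconvergence_error")
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  p <- preset_row(10)
  fit <- fit_kinetics(preset_curve(10), p$A0_mM, n_starts = 2, seed = 0)
  td <- tidy(fit)
  expect_identical(td$term, c("k1", "k2", "k3", "alpha", "baseline"))
  expect_true(all(td$estimate[1:4] > 0))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  aug <- generics::augment(fit)
  expect_true(all(c("time_min", "od340", ".fitted") %in% names(aug)))
  expect_lt(max(abs(aug$.fitted - aug$od340)), 1e-6)
})
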