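test_that("the reaction right-hand side matches hand evaluation", {
  r <- rate_constants(1e-3, 1e-2, 5e-3)

  # only nucleation acts from the all-monomer state
  d <- assembly_rhs(c(A = 0.2, B = 0, N = 0), r)
  expect_equal(unname(d), c(-1e-3 * 0.2, 1e-3 * 0.2, 1e-3 * 0.2))

  # nothing happens without nucleation or fibrils
  d0 <- assembly_rhs(c(A = 0.2, B = 0, N = 0), rate_constants(0, 1e-2, 5e-3))
  expect_equal(unname(d0), c(0, 0, 0))

  # end-catalytic elongation term: dA = -(k1 A + k2 A N)
  d2 <- assembly_rhs(c(A = 0.1, B = 0.05, N = 0.01),
                     rate_constants(1e-3, 1e-2, 0), "end-catalytic")
  expect_equal(d2[["A"]], -1.1e-4)

  # mass-autocatalytic uses B as the catalytic weight
  d3 <- assembly_rhs(c(A = 0.1, B = 0.05, N = 0.01),
                     rate_constants(1e-3, 1e-2, 0), "mass-autocatalytic")
  expect_equal(d3[["A"]], -(1e-3 * 0.1 + 1e-2 * 0.1 * 0.05))

  # total monomer is conserved exactly by construction
  expect_identical(d2[["A"]] + d2[["B"]], 0)

  expect_error(assembly_rhs(c(A = 0.1, B = 0, N = 0), r, "sideways"),
               class = "fibrilkin_config_error")
  expect_error(assembly_rhs(c(A = -0.1, B = 0, N = 0), r),
               class = "fibrilkin_domain_error")
})

test_that("integration conserves monomer and is monotone for both variants", {
  set.seed(42)
  for (i in 1:8) {
    r <- rate_constants(10^runif(1, -4, -2), 10^runif(1, -3, -1),
                        10^runif(1, -3, -1))
    A0 <- runif(1, 0.05, 1.5)
    variant <- sample(c("end-catalytic", "mass-autocatalytic"), 1)
    tr <- integrate_assembly(r, A0, seq(0, 5000, 25), variant)
    expect_lte(max(abs(tr$A_mM + tr$B_mM - A0)), 1e-6 * A0)
    expect_true(all(diff(tr$A_mM) <= 1e-9 * A0))
    expect_true(all(diff(tr$B_mM) >= -1e-9 * A0))
    # a fibril holds at least one monomer
    expect_true(all(tr$N_mM <= tr$B_mM + 1e-8 * A0))
  }
})

test_that("without nucleation nothing assembles", {
  tr <- integrate_assembly(rate_constants(0, 1e-2, 1e-2), 0.5,
                           seq(0, 2000, 20))
  expect_equal(tr$A_mM, rep(0.5, nrow(tr)), tolerance = 1e-9)
  expect_equal(max(tr$B_mM), 0, tolerance = 1e-12)
})

test_that("initial conversion rate equals k1 * A0 for both variants", {
  for (variant in c("end-catalytic", "mass-autocatalytic")) {
    r <- rate_constants(2e-3, 1e-2, 3e-3)
    tr <- integrate_assembly(r, 0.5, seq(0, 1, 0.01), variant)
    slope0 <- (tr$B_mM[2] - tr$B_mM[1]) / 0.01
    expect_equal(slope0, 2e-3 * 0.5, tolerance = 1e-3)
  }
})

test_that("mass-autocatalytic integration with k3 = 0 matches Finke-Watzky", {
  set.seed(7)
  for (i in 1:6) {
    k1 <- 10^runif(1, -4, -2); k2 <- 10^runif(1, -3, -1)
    A0 <- runif(1, 0.05, 1.5)
    t50 <- log(1 + k2 * A0 / k1) / (k1 + k2 * A0)  # closed-form midpoint scale
    times <- seq(0, 10 * t50, length.out = 200)
    tr <- integrate_assembly(rate_constants(k1, k2, 0), A0, times,
                             "mass-autocatalytic")
    expect_equal(tr$A_mM, finke_watzky(times, k1, k2, A0),
                 tolerance = 1e-6)
  }
})

test_that("the closed form behaves at its algebraic limits", {
  expect_identical(finke_watzky(0, 1e-3, 1e-2, 0.5), 0.5)
  a <- finke_watzky(seq(0, 1e5, length.out = 50), 1e-3, 1e-2, 0.5)
  expect_true(all(diff(a) < 0))
  expect_lt(a[50], 1e-6)
  expect_error(finke_watzky(10, 1e-3, 0, 0.5),
               class = "fibrilkin_domain_error")
  expect_error(finke_watzky(10, 1e-3, 1e-2, 0),
               class = "fibrilkin_domain_error")
})

test_that("mean fibril length tracks B/N with degenerate starts as missing", {
  # nucleation only: every fibril is a single-monomer nucleus
  tr <- integrate_assembly(rate_constants(1e-3, 0, 0), 0.5, seq(0, 4000, 40))
  L <- mean_length_trajectory(tr)
  expect_true(is.na(L$mean_length[1]))  # B = N = 0 at t = 0
  expect_equal(L$mean_length[-1], rep(1, nrow(tr) - 1), tolerance = 1e-6)

  # end-joining reduces fibril number at fixed mass: mean length grows
  base <- rate_constants(1.4e-3, 6.5e-3, 3.4e-3)
  doubled <- rate_constants(1.4e-3, 6.5e-3, 6.8e-3)
  t <- seq(0, 5000, 50)
  L1 <- mean_length_trajectory(integrate_assembly(base, 0.103, t))
  L2 <- mean_length_trajectory(integrate_assembly(doubled, 0.103, t))
  expect_gt(utils::tail(L2$mean_length, 1), utils::tail(L1$mean_length, 1))
})

test_that("mass-to-molar conversion follows c * 1000 / MW", {
  expect_identical(mg_per_ml_to_mM(0), 0)
  expect_equal(mg_per_ml_to_mM(1, 9700), 0.1031, tolerance = 1e-3)
  expect_equal(mg_per_ml_to_mM(10, 9700), 10 * mg_per_ml_to_mM(1, 9700))
  expect_error(mg_per_ml_to_mM(1, 0), class = "fibrilkin_domain_error")
  expect_error(mg_per_ml_to_mM(-1), class = "fibrilkin_domain_error")
})

test_that("rate constants reject negative or non-finite values", {
  expect_error(rate_constants(-1e-3, 1, 1), class = "fibrilkin_domain_error")
  expect_error(rate_constants(1e-3, Inf, 1), class = "fibrilkin_domain_error")
  expect_error(integrate_assembly(rate_constants(1e-3, 1e-2, 0), -0.5,
                                  seq(0, 10, 1)),
               class = "fibrilkin_domain_error")
  expect_error(integrate_assembly(rate_constants(1e-3, 1e-2, 0), 0.5,
                                  c(0, 5, 5)),
               class = "fibrilkin_domain_error")
})
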