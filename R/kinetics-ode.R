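#' Right-hand side of the assembly reaction scheme
#'
#' Time derivatives of the deterministic three-reaction scheme at a given
#' state. Two readings of the autocatalytic step are supported:
#' `"mass-autocatalytic"` makes elongation proportional to fibrillar mass
#' (`dA/dt = -k1 A - k2 A B`, the classical Finke-Watzky reading), while
#' `"end-catalytic"` makes it proportional to the number of fibrils, i.e.
#' growing ends (`dA/dt = -k1 A - k2 A N`). In both, `dB/dt = -dA/dt` so
#' total monomer `A + B` is conserved exactly, and end-joining removes
#' fibrils in pairs: `dN/dt = k1 A - k3 N^2`.
#'
#' @param state Named numeric with elements `A`, `B`, `N` (all mM, all
#'   non-negative).
#' @param rates A [rate_constants()] object (or coercible).
#' @param variant `"end-catalytic"` (default) or `"mass-autocatalytic"`.
#' @return Named numeric `c(A = dA/dt, B = dB/dt, N = dN/dt)` in mM/min.
#' @examples
#' assembly_rhs(c(A = 0.1, B = 0, N = 0), rate_constants(1e-3, 1e-2, 0))
#' @export
assembly_rhs <- function(state, rates, variant = "end-catalytic") {
  check_variant(variant)
  rates <- as_rate_constants(rates)
  if (!all(c("A", "B", "N") %in% names(state))) {
    abort("`state` must be a named numeric with elements A, B, N.",
          class = "fibrilkin_domain_error")
  }
  A <- state[["A"]]; B <- state[["B"]]; N <- state[["N"]]
  if (any(!is.finite(c(A, B, N))) || any(c(A, B, N) < 0)) {
    abort("Concentrations must be finite and non-negative.",
          class = "fibrilkin_domain_error")
  }
  cat_w <- if (variant == "mass-autocatalytic") B else N
  dA <- -rates$k1 * A - rates$k2 * A * cat_w
  c(A = dA, B = -dA, N = rates$k1 * A - rates$k3 * N^2)
}

# deSolve-facing wrapper; no validation in the hot path
ode_func <- function(t, y, parms) {
  A <- y[1L]; N <- y[3L]
  cat_w <- if (parms$mass) y[2L] else N
  dA <- -parms$k1 * A - parms$k2 * A * cat_w
  list(c(dA, -dA, parms$k1 * A - parms$k3 * N * N))
}

#' Integrate the assembly scheme on a time grid
#'
#' Solves the deterministic scheme from the all-monomer initial condition
#' `(A0, 0, 0)` with a stiff-capable solver (`deSolve::lsoda`, relative
#' tolerance 1e-8, absolute 1e-12).
#'
#' @inheritParams assembly_rhs
#' @param A0 Initial monomer concentration, mM (> 0).
#' @param times Strictly increasing minute grid starting at 0.
#' @param B0,N0 Optional seeded fibrillar monomer / fibril number (mM);
#'   default 0 (monomer is dissolved fresh, assembly starts unseeded).
#' @return An `assembly_trajectory`: a tibble with columns `time_min`,
#'   `A_mM`, `B_mM`, `N_mM` and attributes `A0`, `variant`, `rates`.
#' @examples
#' traj <- integrate_assembly(bmpp_rates(1), A0 = mg_per_ml_to_mM(1),
#'                            times = seq(0, 3000, 10))
#' head(traj)
#' @export
integrate_assembly <- function(rates, A0, times, variant = "end-catalytic",
                               B0 = 0, N0 = 0) {
  check_variant(variant)
  rates <- as_rate_constants(rates)
  if (!is.numeric(A0) || length(A0) != 1L || !is.finite(A0) || A0 <= 0) {
    abort("`A0` must be a single positive concentration in mM.",
          class = "fibrilkin_domain_error")
  }
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing and start at 0.",
          class = "fibrilkin_domain_error")
  }
  parms <- list(k1 = rates$k1, k2 = rates$k2, k3 = rates$k3,
                mass = variant == "mass-autocatalytic")
  sol <- deSolve::lsoda(c(A = A0, B = B0, N = N0), times, ode_func, parms,
                        rtol = 1e-8, atol = 1e-12)
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    abort("ODE solver failed to cover the requested grid; check parameters.",
          class = "fibrilkin_numerical_error")
  }
  out <- tibble::tibble(
    time_min = as.numeric(sol[, "time"]),
    A_mM = pmax(as.numeric(sol[, "A"]), 0),
    B_mM = pmax(as.numeric(sol[, "B"]), 0),
    N_mM = pmax(as.numeric(sol[, "N"]), 0)
  )
  structure(out,
            class = c("assembly_trajectory", class(out)),
            A0 = A0 + B0, variant = variant, rates = rates)
}

#' Closed-form Finke-Watzky monomer decay
#'
#' The two-reaction limit of the scheme (nucleation plus mass-autocatalytic
#' growth, no end-joining) has the closed-form solution
#' \deqn{A(t) = \frac{k_1/k_2 + A_0}{1 + \frac{k_1}{k_2 A_0}
#'       e^{(k_1 + k_2 A_0) t}}.}
#' It is the independent oracle for the numerical integrator when `k3 = 0`
#' under the mass-autocatalytic variant.
#'
#' @param t Time(s), minutes (>= 0).
#' @param k1 Nucleation rate, min^-1 (> 0).
#' @param k2 Growth rate, mM^-1 min^-1 (> 0); `k2 = 0` is an error, the
#'   formula is undefined there (no silent fall-back to first-order decay).
#' @param A0 Initial monomer, mM (> 0).
#' @return Free monomer concentration `A(t)` in mM.
#' @examples
#' finke_watzky(c(0, 100, 1000), k1 = 1.4e-3, k2 = 6.5e-3, A0 = 0.103)
#' @export
finke_watzky <- function(t, k1, k2, A0) {
  if (!is.numeric(k1) || k1 <= 0 || !is.numeric(k2) || k2 <= 0 ||
      !is.numeric(A0) || A0 <= 0) {
    abort("finke_watzky() requires k1 > 0, k2 > 0, A0 > 0.",
          class = "fibrilkin_domain_error")
  }
  if (any(t < 0)) {
    abort("`t` must be non-negative.", class = "fibrilkin_domain_error")
  }
  (k1 / k2 + A0) / (1 + (k1 / (k2 * A0)) * exp((k1 + k2 * A0) * t))
}

#' Mean fibril length along a trajectory
#'
#' Bookkeeping link between the concentration-level model and fibril
#' geometry: the number-average fibril length in monomer units is
#' `L(t) = B(t) / N(t)`. Where no fibrils exist yet (`B = N = 0`) the mean
#' length is undefined and reported as `NA`, not 0.
#'
#' @param traj An `assembly_trajectory` from [integrate_assembly()].
#' @return A tibble `time_min`, `mean_length` (monomer units).
#' @export
mean_length_trajectory <- function(traj) {
  if (!all(c("time_min", "B_mM", "N_mM") %in% names(traj))) {
    abort("`traj` must have columns time_min, B_mM, N_mM.",
          class = "fibrilkin_domain_error")
  }
  tibble::tibble(
    time_min = traj$time_min,
    mean_length = ifelse(traj$N_mM > 0, traj$B_mM / traj$N_mM, NA_real_)
  )
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  cat(sprintf("<assembly_trajectory>  variant = %s, A0 = %g mM, %d samples over %g min\n",
              attr(x, "variant"), attr(x, "A0"), nrow(x), max(x$time_min)))
  NextMethod()
}
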