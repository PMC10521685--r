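#' Exact stochastic simulation of fibril assembly
#'
#' Event-driven (direct-method) realization of the three-reaction scheme
#' with explicit per-fibril lengths, at a resolution of individual monomers.
#' The critical nucleus is one monomer: a nucleation event converts one free
#' monomer into a length-1 fibril. An elongation event adds one monomer to a
#' fibril chosen with probability proportional to the variant's catalytic
#' weight (uniform over fibrils for `"end-catalytic"`; proportional to
#' length for `"mass-autocatalytic"`). A joining event merges a uniformly
#' chosen unordered pair of fibrils, summing their lengths.
#'
#' Concentration-unit rate constants are converted to event propensities
#' with the volume factor `Omega = system_size / A0` (monomer counts per
#' mM), so that ensemble means are directly comparable to
#' [integrate_assembly()]:
#' nucleation `k1 * free`, elongation `(k2/Omega) * free * w` with `w` the
#' catalytic weight, joining `(k3/Omega) * n_fibrils * (n_fibrils - 1)`.
#'
#' @inheritParams integrate_assembly
#' @param system_size Total monomer count at t = 0 (>= 10).
#' @param snapshot_times Minutes at which to record the population;
#'   non-empty, non-negative, increasing.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A `fibril_populations` tibble with one row per snapshot:
#'   `time_min`, `free` (free monomer count), `n_fibrils`, and `lengths`
#'   (list-column of integer fibril lengths in monomer units). Attributes
#'   `system_size`, `A0`, `omega`, `variant`, `rates`.
#' @examples
#' pops <- simulate_fibrils(bmpp_rates(1), system_size = 500,
#'                          A0 = mg_per_ml_to_mM(1),
#'                          snapshot_times = c(100, 500, 2000), seed = 1)
#' pops
#' @export
simulate_fibrils <- function(rates, system_size, A0, snapshot_times,
                             variant = "end-catalytic", seed = 1L) {
  check_variant(variant)
  rates <- as_rate_constants(rates)
  if (!is.numeric(system_size) || system_size < 10) {
    abort("`system_size` must be at least 10 monomers.",
          class = "fibrilkin_domain_error")
  }
  if (!is.numeric(A0) || A0 <= 0) {
    abort("`A0` must be positive (mM).", class = "fibrilkin_domain_error")
  }
  if (length(snapshot_times) == 0L || any(snapshot_times < 0) ||
      any(diff(snapshot_times) <= 0) && length(snapshot_times) > 1L) {
    abort("`snapshot_times` must be non-empty, non-negative and increasing.",
          class = "fibrilkin_domain_error")
  }
  system_size <- as.integer(system_size)
  omega <- system_size / A0
  k1 <- rates$k1; k2c <- rates$k2 / omega; k3c <- rates$k3 / omega
  mass <- variant == "mass-autocatalytic"

  withr::local_seed(as.integer(seed))

  lengths <- integer(system_size)   # slots 1..nf hold live fibril lengths
  nf <- 0L
  free <- system_size
  poly <- 0L                        # total polymerized monomers
  t_now <- 0
  snaps <- vector("list", length(snapshot_times))
  next_snap <- 1L

  record_through <- function(upto) {
    while (next_snap <= length(snapshot_times) &&
           snapshot_times[next_snap] <= upto) {
      snaps[[next_snap]] <<- list(time_min = snapshot_times[next_snap],
                                  free = free,
                                  lengths = lengths[seq_len(nf)])
      next_snap <<- next_snap + 1L
    }
  }
  if (any(snapshot_times == 0)) record_through(0)

  repeat {
    a1 <- k1 * free
    a2 <- k2c * free * (if (mass) poly else nf)
    a3 <- if (nf > 1L) k3c * nf * (nf - 1) else 0
    a0 <- a1 + a2 + a3
    if (a0 <= 0) break
    t_now <- t_now + rexp(1L, a0)
    record_through(min(t_now, Inf))
    if (next_snap > length(snapshot_times)) break
    u <- runif(1L) * a0
    if (u < a1) {                       # nucleation: free monomer -> new fibril
      nf <- nf + 1L
      lengths[nf] <- 1L
      free <- free - 1L
      poly <- poly + 1L
    } else if (u < a1 + a2) {           # elongation: add one monomer
      i <- if (mass) {
        sample.int(nf, 1L, prob = lengths[seq_len(nf)])
      } else {
        sample.int(nf, 1L)
      }
      lengths[i] <- lengths[i] + 1L
      free <- free - 1L
      poly <- poly + 1L
    } else {                            # joining: merge a uniform pair
      ij <- sample.int(nf, 2L)
      lengths[min(ij)] <- lengths[ij[1L]] + lengths[ij[2L]]
      lengths[max(ij)] <- lengths[nf]   # swap-delete the second fibril
      nf <- nf - 1L
    }
  }
  record_through(Inf)                   # system exhausted: state is final

  out <- tibble::tibble(
    time_min = purrr::map_dbl(snaps, "time_min"),
    free = purrr::map_int(snaps, "free"),
    n_fibrils = purrr::map_int(snaps, ~ length(.x$lengths)),
    lengths = purrr::map(snaps, "lengths")
  )
  structure(out, class = c("fibril_populations", class(out)),
            system_size = system_size, A0 = A0, omega = omega,
            variant = variant, rates = rates, seed = as.integer(seed))
}

#' Fibril geometry summaries of a stochastic population
#'
#' Converts monomer-unit fibril lengths to AFM-comparable contour lengths
#' and aspect ratios. Contour length per fibril is
#' `length * rise_per_monomer`; aspect ratio is contour length over the
#' (constant) fibril diameter. Mean and sample SD are taken over fibrils.
#'
#' @param pops A `fibril_populations` tibble from [simulate_fibrils()], or a
#'   bare numeric vector of lengths (monomer units).
#' @param rise_per_monomer Contour length contributed per monomer, nm.
#' @param diameter_nm Fibril diameter, nm (AFM reports ~10 nm, constant).
#' @return A tibble with one row per snapshot: `time_min`, `n_fibrils`,
#'   `mean_contour_nm`, `sd_contour_nm`, `mean_aspect`.
#' @examples
#' population_stats(rep(100, 50), rise_per_monomer = 6.28, diameter_nm = 10)
#' @export
population_stats <- function(pops, rise_per_monomer, diameter_nm) {
  if (!is.numeric(rise_per_monomer) || rise_per_monomer <= 0 ||
      !is.numeric(diameter_nm) || diameter_nm <= 0) {
    abort("`rise_per_monomer` and `diameter_nm` must be positive (nm).",
          class = "fibrilkin_domain_error")
  }
  if (is.numeric(pops)) {
    pops <- tibble::tibble(time_min = NA_real_, lengths = list(pops))
  }
  if (any(purrr::map_int(pops$lengths, length) == 0L)) {
    abort("No fibrils in at least one population; nothing to summarize.",
          class = "fibrilkin_empty_error")
  }
  dplyr::mutate(
    tibble::tibble(time_min = pops$time_min),
    n_fibrils = purrr::map_int(pops$lengths, length),
    mean_contour_nm = purrr::map_dbl(pops$lengths,
                                     ~ mean(.x) * rise_per_monomer),
    sd_contour_nm = purrr::map_dbl(
      pops$lengths,
      ~ if (length(.x) > 1L) sd(.x) * rise_per_monomer else NA_real_),
    mean_aspect = .data$mean_contour_nm / diameter_nm
  )
}

#' Contour-length histogram of fibril populations
#'
#' @inheritParams population_stats
#' @param bin_width_nm Histogram bin width, nm (> 0). Bins are
#'   `[0, w), [w, 2w), ...`; counts sum to the number of fibrils.
#' @return A tibble `time_min`, `bin_lo_nm`, `bin_hi_nm`, `count`.
#' @export
length_distribution <- function(pops, bin_width_nm, rise_per_monomer) {
  if (!is.numeric(bin_width_nm) || bin_width_nm <= 0) {
    abort("`bin_width_nm` must be positive.", class = "fibrilkin_domain_error")
  }
  if (is.numeric(pops)) {
    pops <- tibble::tibble(time_min = NA_real_, lengths = list(pops))
  }
  purrr::map2_dfr(pops$time_min, pops$lengths, function(tm, len) {
    contour <- len * rise_per_monomer
    bin <- floor(contour / bin_width_nm)
    tab <- table(bin)
    tibble::tibble(
      time_min = tm,
      bin_lo_nm = as.numeric(names(tab)) * bin_width_nm,
      bin_hi_nm = (as.numeric(names(tab)) + 1) * bin_width_nm,
      count = as.integer(tab)
    )
  })
}

#' @export
print.fibril_populations <- function(x, ...) {
  cat(sprintf(
    "<fibril_populations>  %s, system_size = %d (A0 = %g mM), %d snapshot(s)\n",
    attr(x, "variant"), attr(x, "system_size"), attr(x, "A0"), nrow(x)))
  NextMethod()
}
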