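#' Rate constants of the three-reaction assembly scheme
#'
#' Bundles the kinetic parameters of the nucleation / autocatalytic-growth /
#' end-joining scheme for a self-assembling polypeptide:
#' \deqn{A \xrightarrow{k_1} B \qquad A + B \xrightarrow{k_2} 2B \qquad
#'       B + B \xrightarrow{k_3} 2B}
#' where `A` is the free monomer, `B` fibrillar (converted) monomer, and the
#' third reaction merges two fibrils end-to-end (it leaves `A` and `B`
#' unchanged but reduces the fibril number concentration `N`).
#'
#' Units: `k1` is first order (per minute); `k2` and `k3` are second order
#' (per mM per minute).
#'
#' @param k1 Nucleation rate constant, min^-1.
#' @param k2 Growth-by-monomer-addition rate constant, mM^-1 min^-1.
#' @param k3 Fibril end-joining rate constant, mM^-1 min^-1.
#' @return An object of class `rate_constants`: a named list with elements
#'   `k1`, `k2`, `k3`.
#' @examples
#' rate_constants(1.4e-3, 6.5e-3, 3.4e-3)
#' @export
rate_constants <- function(k1, k2, k3) {
  for (nm in c("k1", "k2", "k3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "fibrilkin_domain_error")
    }
    if (v < 0) {
      abort(sprintf("`%s` must be non-negative (got %g).", nm, v),
            class = "fibrilkin_domain_error")
    }
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "<rate_constants>  k1 = %g min^-1,  k2 = %g mM^-1 min^-1,  k3 = %g mM^-1 min^-1\n",
    x$k1, x$k2, x$k3))
  invisible(x)
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(rate_constants(x[[1]], x[[2]], x[[3]]))
  if (is.list(x) && all(c("k1", "k2", "k3") %in% names(x))) {
    return(rate_constants(x$k1, x$k2, x$k3))
  }
  abort("Cannot interpret `rates`: supply rate_constants() or a length-3 numeric.",
        class = "fibrilkin_domain_error")
}

#' Convert a mass concentration to molar units
#'
#' @param c_mg_ml Concentration in mg/ml.
#' @param mw_da Monomer molecular weight in Daltons. Defaults to 9700 Da,
#'   the BMPP monomer mass from MALDI-MS (the 19.3 kDa species is the dimer
#'   ion and is not used).
#' @return Concentration in mM.
#' @examples
#' mg_per_ml_to_mM(1)    # 0.1031 mM at 9.7 kDa
#' mg_per_ml_to_mM(10)   # 1.031 mM
#' @export
mg_per_ml_to_mM <- function(c_mg_ml, mw_da = 9700) {
  if (!is.numeric(mw_da) || length(mw_da) != 1L || !is.finite(mw_da) || mw_da <= 0) {
    abort("`mw_da` must be a single positive number.",
          class = "fibrilkin_domain_error")
  }
  if (any(!is.finite(c_mg_ml)) || any(c_mg_ml < 0)) {
    abort("`c_mg_ml` must be finite and non-negative.",
          class = "fibrilkin_domain_error")
  }
  c_mg_ml * 1000 / mw_da
}

#' Published BMPP assembly presets
#'
#' The rate constants and AFM fibril geometry reported for BMPP assembly at
#' 1, 5 and 10 mg/ml, with the matching molar concentration at the 9.7 kDa
#' monomer mass. These are the generating truths used throughout the
#' synthetic-data round trips.
#'
#' @return A tibble with one row per concentration: `conc_mg_ml`, `A0_mM`,
#'   `k1`, `k2`, `k3`, `diameter_nm`, `length_mean_nm`, `length_sd_nm`,
#'   `aspect_ratio`.
#' @examples
#' bmpp_presets()
#' @export
bmpp_presets <- function() {
  tibble::tibble(
    conc_mg_ml     = c(1, 5, 10),
    A0_mM          = mg_per_ml_to_mM(c(1, 5, 10)),
    k1             = c(1.4e-3, 1.6e-3, 9.9e-3),
    k2             = c(6.5e-3, 1.6e-2, 7.4e-3),
    k3             = c(3.4e-3, 4.8e-3, 4.9e-3),
    diameter_nm    = 10,
    length_mean_nm = c(579, 578, 628),
    length_sd_nm   = c(115, 86, 94),
    aspect_ratio   = c(60, 60, 63)
  )
}

#' @rdname bmpp_presets
#' @param conc_mg_ml One of 1, 5 or 10 (mg/ml).
#' @return `bmpp_rates()`: the `rate_constants` for one preset.
#' @export
bmpp_rates <- function(conc_mg_ml) {
  p <- bmpp_presets()
  i <- match(conc_mg_ml, p$conc_mg_ml)
  if (is.na(i)) {
    abort("No preset at this concentration: use 1, 5 or 10 mg/ml.",
          class = "fibrilkin_config_error")
  }
  rate_constants(p$k1[i], p$k2[i], p$k3[i])
}

check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% c("end-catalytic", "mass-autocatalytic")) {
    abort(
      "`variant` must be \"end-catalytic\" or \"mass-autocatalytic\".",
      class = "fibrilkin_config_error")
  }
  variant
}
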