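#' Generate a synthetic turbidity curve
#'
#' Integrates the assembly scheme, applies the linear OD340 observation
#' model, samples every `sampling_interval` minutes (the acquisition cadence
#' of the emulated instrument, 10 min), and adds independent Gaussian noise.
#' Deterministic given `(parameters, seed)`.
#'
#' @inheritParams integrate_assembly
#' @param alpha OD per mM of fibrillar monomer.
#' @param baseline Baseline OD.
#' @param t_max Final time, minutes.
#' @param sampling_interval Sampling cadence, minutes (default 10).
#' @param noise_sd Gaussian noise SD in OD units; 0 gives the noise-free
#'   observation exactly.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A `kinetic_curve` tibble `time_min`, `od340`.
#' @export
gen_turbidity <- function(rates, A0, alpha = 1, baseline = 0,
                          t_max = 3000, sampling_interval = 10,
                          variant = "end-catalytic",
                          noise_sd = 0, seed = 1L) {
  times <- seq(0, t_max, by = sampling_interval)
  traj <- integrate_assembly(rates, A0, times, variant)
  curve <- observe_turbidity(traj, alpha, baseline)
  if (noise_sd > 0) {
    withr::local_seed(as.integer(seed))
    curve$od340 <- curve$od340 + rnorm(nrow(curve), 0, noise_sd)
  }
  curve
}

#' Generate a timestamped CD spectra series from a trajectory
#'
#' Emulates CD monitoring of the coil-to-helix transition during assembly:
#' the helix fraction tracks the converted fraction,
#' `f_helix(t) = B(t)/A0`, and each spectrum is the convex combination
#' `f * helix + (1 - f) * coil` of the basis plus Gaussian noise.
#'
#' @param traj An `assembly_trajectory`.
#' @param basis A `cd_basis` from [cd_reference_basis()].
#' @param noise_sd Gaussian noise SD in ellipticity units (0 = noiseless).
#' @param seed Integer seed.
#' @return A tibble `time_min`, `f_true`, `spectrum` (list-column of
#'   tibbles `wavelength_nm`, `ellipticity`).
#' @export
gen_cd_series <- function(traj, basis = cd_reference_basis(),
                          noise_sd = 0, seed = 1L) {
  A0 <- attr(traj, "A0") %||% max(traj$A_mM + traj$B_mM)
  f <- pmin(pmax(traj$B_mM / A0, 0), 1)
  withr::local_seed(as.integer(seed))
  spectra <- purrr::map(f, function(fi) {
    e <- fi * basis$helix + (1 - fi) * basis$coil
    if (noise_sd > 0) e <- e + rnorm(length(e), 0, noise_sd)
    tibble::tibble(wavelength_nm = basis$wavelength_nm, ellipticity = e)
  })
  tibble::tibble(time_min = traj$time_min, f_true = f, spectrum = spectra)
}

#' Generate AFM-like fibril contour-length samples
#'
#' Draws positive contour lengths from a lognormal distribution with its
#' first two moments matched to the requested mean and SD (as reported from
#' AFM tracing, e.g. 579 +/- 115 nm at equilibrium).
#'
#' @param n Sample size (>= 1).
#' @param mean_nm,sd_nm Target mean and SD of contour length, nm (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` lengths in nm, all positive.
#' @export
gen_fibril_lengths <- function(n, mean_nm, sd_nm, seed = 1L) {
  if (n < 1 || mean_nm <= 0 || sd_nm <= 0) {
    abort("Require n >= 1 and positive mean/sd.",
          class = "fibrilkin_domain_error")
  }
  sdlog2 <- log(1 + (sd_nm / mean_nm)^2)
  meanlog <- log(mean_nm) - sdlog2 / 2
  withr::local_seed(as.integer(seed))
  rlnorm(n, meanlog, sqrt(sdlog2))
}

#' Generate a balanced qPCR Ct table with known effects
#'
#' Each gene starts from a base Ct; a true log2 expression effect of `e`
#' in a group lowers its Ct by `e` cycles (one cycle per doubling), and
#' replicate noise is Gaussian on the cycle scale. The reference gene must
#' carry zero effect everywhere (it is the normalization anchor).
#'
#' @param effects A tibble with columns `gene`, `group`,
#'   `log2_effect` giving the true log2 fold change of each gene in each
#'   non-control group (unlisted pairs default to 0).
#' @param genes Character vector of gene names (must include `ref_gene`).
#' @param groups Character vector of group labels; the first is the control.
#' @param ref_gene Reference gene name.
#' @param n_replicates Replicates per (gene, group) cell (default 3,
#'   triplicate qPCR).
#' @param noise_sd_cycles Gaussian Ct noise SD, cycles (default 0.1).
#' @param base_ct Named numeric of per-gene base Ct, or a single value
#'   (default 20) used for all genes.
#' @param seed Integer seed.
#' @return A tibble `gene`, `group`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(genes, groups, effects = NULL, ref_gene = "actin",
                         n_replicates = 3L, noise_sd_cycles = 0.1,
                         base_ct = 20, seed = 1L) {
  if (!ref_gene %in% genes) {
    abort("`genes` must include the reference gene.",
          class = "fibrilkin_domain_error")
  }
  if (!is.null(effects)) {
    if (!all(c("gene", "group", "log2_effect") %in% names(effects))) {
      abort("`effects` needs columns gene, group, log2_effect.",
            class = "fibrilkin_domain_error")
    }
    if (any(effects$gene == ref_gene & effects$log2_effect != 0)) {
      abort("The reference gene cannot carry a nonzero effect.",
            class = "fibrilkin_domain_error")
    }
  }
  if (length(base_ct) == 1L && is.null(names(base_ct))) {
    base_ct <- setNames(rep(base_ct, length(genes)), genes)
  }
  grid <- tidyr::expand_grid(gene = genes, group = groups,
                             replicate = seq_len(n_replicates))
  eff <- if (is.null(effects)) {
    tibble::tibble(gene = character(), group = character(),
                   log2_effect = numeric())
  } else effects
  out <- grid |>
    dplyr::left_join(eff, by = c("gene", "group")) |>
    dplyr::mutate(log2_effect = dplyr::coalesce(.data$log2_effect, 0),
                  ct = unname(base_ct[.data$gene]) - .data$log2_effect)
  if (noise_sd_cycles > 0) {
    withr::local_seed(as.integer(seed))
    out$ct <- out$ct + rnorm(nrow(out), 0, noise_sd_cycles)
  }
  dplyr::select(out, "gene", "group", "replicate", "ct")
}
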