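#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: species
#' trajectories, turbidity curves (with the fitted curve overlaid for a
#' `kinetics_fit`), fibril length histograms, and helix-fraction
#' transitions.
#'
#' @param object The object to plot.
#' @param ... Passed on where noted; otherwise unused.
#' @return A ggplot.
#' @name fibrilkin_plots
NULL

#' @rdname fibrilkin_plots
#' @method autoplot assembly_trajectory
#' @export
autoplot.assembly_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("A_mM", "B_mM", "N_mM"),
                              names_to = "species", values_to = "conc_mM")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Concentration (mM)",
                  colour = NULL,
                  title = sprintf("Assembly trajectory (%s)",
                                  attr(object, "variant")))
}

#' @rdname fibrilkin_plots
#' @method autoplot kinetic_curve
#' @export
autoplot.kinetic_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_min, .data$od340)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (min)", y = "OD340")
}

#' @rdname fibrilkin_plots
#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$od340), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red") +
    ggplot2::labs(x = "Time (min)", y = "OD340",
                  title = "Turbidity fit (points: data, line: model)")
}

#' @rdname fibrilkin_plots
#' @param bin_width_nm,rise_per_monomer Histogram geometry, passed to
#'   [length_distribution()].
#' @method autoplot fibril_populations
#' @export
autoplot.fibril_populations <- function(object, bin_width_nm = 50,
                                        rise_per_monomer = 1, ...) {
  hist <- length_distribution(object, bin_width_nm, rise_per_monomer)
  ggplot2::ggplot(hist, ggplot2::aes(x = (.data$bin_lo_nm + .data$bin_hi_nm) / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = bin_width_nm * 0.9) +
    ggplot2::facet_wrap(~time_min, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Contour length (nm)", y = "Fibrils")
}

#' @rdname fibrilkin_plots
#' @method autoplot cd_transition
#' @export
autoplot.cd_transition <- function(object, ...) {
  fr <- object$fractions
  fit <- tibble::tibble(
    time_min = seq(min(fr$time_min), max(fr$time_min), length.out = 200),
  )
  fit$f_helix <- object$f_inf + (object$f0 - object$f_inf) *
    exp(-object$rate_per_min * fit$time_min)
  ggplot2::ggplot(fr, ggplot2::aes(.data$time_min, .data$f_helix)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::labs(x = "Time (min)", y = "Helix fraction")
}

#' Bar plot of ddCt fold changes by gene and group
#'
#' @param summary Output of [fold_change_summary()].
#' @return A ggplot.
#' @export
plot_fold_changes <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$mean_fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fold - .data$sd_fold,
                   ymax = .data$mean_fold + .data$sd_fold),
      width = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Delta * C[t]}))
}
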