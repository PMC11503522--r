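#' Plot a mass spectrum
#'
#' @param object A tibble with columns `mz`, `intensity` (e.g. from
#'   [simulate_spectrum()] or [read_spectrum()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Th)", y = "Intensity") +
    ggplot2::theme_minimal()
}

#' Plot a zero-charge mass spectrum with its charge marginal
#'
#' @param object A `zero_charge_spectrum` from [deconvolve()].
#' @param which `"mass"` for the zero-charge spectrum or `"charge"` for
#'   the charge-state marginal.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zero_charge_spectrum <- function(object, which = c("mass", "charge"), ...) {
  which <- match.arg(which)
  if (which == "mass") {
    ggplot2::ggplot(object$mass_spectrum,
                    ggplot2::aes(x = .data$mass, y = .data$intensity)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "Mass (Da)", y = "Intensity") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$charge_marginal,
                    ggplot2::aes(x = .data$z, y = .data$intensity)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Charge state z", y = "Allocated intensity") +
      ggplot2::theme_minimal()
  }
}

#' Plot a sequential binding fit
#'
#' Observed mole fractions (points) and the fitted sequential-model curves
#' (lines) against total lipid concentration, one colour per bound state.
#'
#' @param object A `kd_fit` from [fit_sequential_kds()].
#' @param n_curve Number of lipid concentrations at which the fitted
#'   curves are evaluated.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kd_fit <- function(object, n_curve = 101, ...) {
  long_obs <- tidyr::pivot_longer(object$titration,
                                  dplyr::matches("^f[0-9]+$"),
                                  names_to = "state", values_to = "mole_fraction")
  lgrid <- seq(min(object$titration$l_total_uM),
               max(object$titration$l_total_uM), length.out = n_curve)
  lf <- free_lipid(object$kd_hat, object$p_total, lgrid)
  pred <- binding_fractions(lf, object$kd_hat)
  curves <- tibble::as_tibble(stats::setNames(as.data.frame(pred),
                                              paste0("f", 0:object$n_sites)))
  curves$l_total_uM <- lgrid
  long_fit <- tidyr::pivot_longer(curves, dplyr::matches("^f[0-9]+$"),
                                  names_to = "state", values_to = "mole_fraction")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$l_total_uM,
                                         y = .data$mole_fraction,
                                         colour = .data$state)) +
    ggplot2::geom_point(data = long_obs) +
    ggplot2::geom_line(data = long_fit) +
    ggplot2::labs(x = "Total lipid (uM)", y = "Mole fraction",
                  colour = "Bound state") +
    ggplot2::theme_minimal()
}

#' Plot per-site dissociation constants from replicate fits
#'
#' @param summary A tibble from [replicate_summary()].
#' @return A ggplot of mean Kd per site with +/- sd error bars on a log
#'   scale.
#' @export
plot_kd_ladder <- function(summary) {
  stopifnot(all(c("site", "kd_mean_uM", "kd_sd_uM") %in% names(summary)))
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data$site),
                                        y = .data$kd_mean_uM)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$kd_mean_uM - .data$kd_sd_uM, .Machine$double.eps),
      ymax = .data$kd_mean_uM + .data$kd_sd_uM), width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Lipid binding event", y = "Kd (uM)") +
    ggplot2::theme_minimal()
}
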