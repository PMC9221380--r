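#' Tidy methods for simulation results and fits
#'
#' Broom-style summaries: `tidy()` returns one row per estimated
#' quantity (per neuron, per parameter), `glance()` a one-row model
#' summary.
#'
#' @param x an `lc_sim`, `kernel_fit`, `nn_fit` or `nn_result` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy-methods
NULL

#' @rdname tidy-methods
#' @export
tidy.lc_sim <- function(x, ...) {
  purrr::map_dfr(seq_along(x$spikes), function(i) {
    dplyr::bind_cols(
      tibble::tibble(neuron = i),
      spike_train_features(x$spikes[[i]], 0, x$config$duration_ms))
  })
}

#' @rdname tidy-methods
#' @export
glance.lc_sim <- function(x, ...) {
  tibble::tibble(n_neurons = length(x$spikes),
                 duration_ms = x$config$duration_ms,
                 dt = x$config$dt,
                 n_releases = nrow(x$releases),
                 seed = x$meta$seed %||% NA_integer_,
                 config_hash = x$meta$config_hash)
}

#' @rdname tidy-methods
#' @export
tidy.kernel_fit <- function(x, ...) {
  tibble::tibble(term = c("tau_fast", "tau_slow", "attenuation"),
                 estimate = c(x$tau_fast, x$tau_slow, x$attenuation))
}

#' @rdname tidy-methods
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(tau_fast = x$tau_fast, tau_slow = x$tau_slow,
                 attenuation = x$attenuation, t_peak = x$t_peak,
                 sigma = x$sigma)
}

#' @rdname tidy-methods
#' @export
tidy.nn_fit <- function(x, ...) {
  tibble::tibble(term = c("gamma", "lambda_long", "lambda_short"),
                 estimate = c(x$gamma, x$lambda_long, x$lambda_short))
}

#' @rdname tidy-methods
#' @export
glance.nn_fit <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, lambda_long = x$lambda_long,
                 lambda_short = x$lambda_short, logLik = x$logLik,
                 n = x$n, convergence = x$convergence)
}

#' @rdname tidy-methods
#' @export
glance.nn_result <- function(x, ...) {
  tibble::tibble(n = x$n, median_um = x$median_um,
                 fraction_within = x$fraction_within,
                 radius_um = x$radius_um)
}

#' Plot a simulation result
#'
#' Voltage, calcium and GIRK-conductance traces, one facet row per
#' variable, coloured by neuron.
#'
#' @param object an `lc_sim` object.
#' @param vars variables to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lc_sim <- function(object, vars = c("v_s", "ca", "g_girk"), ...) {
  long <- tidyr::pivot_longer(object$trace, cols = dplyr::all_of(vars),
                              names_to = "variable")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value,
                                     colour = factor(.data$neuron))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable),
                        scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot an attenuation map
#'
#' @param object a `concentration_field` from [attenuation_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.concentration_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_ms, .data$r_um,
                                       fill = log10(.data$c_over_c0))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 C/C0") +
    ggplot2::labs(x = "time (ms)", y = "distance (um)") +
    ggplot2::theme_minimal()
}

#' Plot a nearest-neighbour summary
#'
#' Histogram of NN distances with the interaction radius marked; if a
#' fit is supplied its scaled density is overlaid.
#'
#' @param object an `nn_result` from [nn_summary()].
#' @param fit optional `nn_fit` from [fit_nn_distribution()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nn_result <- function(object, fit = NULL, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h) +
    ggplot2::geom_col(ggplot2::aes((.data$bin_lo + .data$bin_hi) / 2,
                                   .data$count),
                      width = h$bin_hi[1] - h$bin_lo[1],
                      fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$radius_um,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "nearest-neighbour distance (um)", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    bw <- h$bin_hi[1] - h$bin_lo[1]
    dd <- seq(0.1, max(h$bin_hi), by = 0.5)
    f <- nn_family_density(dd, fit$gamma, fit$lambda_long,
                           fit$lambda_short)
    z <- stats::integrate(nn_family_density, 0, max(h$bin_hi) * 3,
                          gamma = fit$gamma,
                          lambda_long = fit$lambda_long,
                          lambda_short = fit$lambda_short)$value
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(d = dd, y = f / z * object$n * bw),
      ggplot2::aes(.data$d, .data$y), colour = "steelblue")
  }
  p
}

#' Plot an FI curve
#'
#' @param fi a tibble from [fi_protocol()].
#' @return a ggplot object.
#' @export
plot_fi_curve <- function(fi) {
  long <- tidyr::pivot_longer(fi, c("rate_hz", "early_rate_hz"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$amplitude, .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(
      labels = c(early_rate_hz = "first two spikes",
                 rate_hz = "whole step")) +
    ggplot2::labs(x = "step amplitude (uA/cm^2)", y = "spike rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
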