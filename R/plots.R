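#' Plot a spike raster
#'
#' @param object A `spike_raster` from [simulate_network()].
#' @param ... Unused.
#' @param max_points Subsample the raster beyond this many spikes.
#' @return A ggplot object.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ..., max_points = 50000) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[sort(sample.int(nrow(df), max_points)), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$neuron,
                                   colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(exc = "#2e7d32", inh = "#c62828")) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot population rate series
#'
#' @param object A [population_rate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_rate
#' @export
autoplot.population_rate <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$t, y = .data$rate,
                               colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(exc = "#2e7d32", inh = "#c62828")) +
    ggplot2::labs(x = "time (ms)", y = "population rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a measured transfer function (and optionally its fit)
#'
#' @param object A `tf_measurement` or `tf_fit`.
#' @param ... Unused.
#' @return A ggplot object: measured rates as dots (with standard-error
#'   bars), fitted curves as lines, one colour per inhibitory background.
#' @method autoplot tf_measurement
#' @export
autoplot.tf_measurement <- function(object, ...) {
  df <- as_tibble(object)
  df$nu_i_f <- factor(df$nu_i)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu_e, y = .data$rate,
                                   colour = .data$nu_i_f)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$sem,
                                        ymax = .data$rate + .data$sem),
                           width = 0, na.rm = TRUE) +
    ggplot2::labs(x = expression(nu[e] ~ "(Hz)"), y = "output rate (Hz)",
                  colour = expression(nu[i])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tf_measurement
#' @method autoplot tf_fit
#' @export
autoplot.tf_fit <- function(object, ...) {
  df <- object$samples
  df$nu_i_f <- factor(df$nu_i)
  curves <- purrr::map_dfr(unique(df$nu_i), function(ni) {
    sub <- df[df$nu_i == ni, ]
    nu_e <- seq(min(sub$nu_e), max(sub$nu_e), length.out = 80)
    tibble(nu_e = nu_e, nu_i = ni,
           rate = predicted_rate(nu_e, ni, object$tf))
  })
  curves$nu_i_f <- factor(curves$nu_i)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu_e, y = .data$rate,
                                   colour = .data$nu_i_f)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = expression(nu[e] ~ "(Hz)"), y = "output rate (Hz)",
                  colour = expression(nu[i])) +
    ggplot2::theme_minimal()
}

#' Plot a mean-field trajectory
#'
#' Population rates over time with a one-standard-deviation ribbon from the
#' covariance diagonal, plus the stimulus envelope.
#'
#' @param object A trajectory from [integrate_mean_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mf_trajectory
#' @export
autoplot.mf_trajectory <- function(object, ...) {
  long <- tibble(
    t = rep(object$t, 2),
    population = rep(c("exc", "inh"), each = nrow(object)),
    rate = c(object$nu_e, object$nu_i),
    sd = sqrt(pmax(c(object$c_ee, object$c_ii), 0)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$rate,
                                     colour = .data$population,
                                     fill = .data$population)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - .data$sd,
                                      ymax = .data$rate + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = tibble(t = object$t, rate = object$stim_rate,
                                     population = "stimulus", sd = 0),
                       linetype = "dashed", colour = "black") +
    ggplot2::scale_colour_manual(values = c(exc = "#2e7d32", inh = "#c62828")) +
    ggplot2::scale_fill_manual(values = c(exc = "#2e7d32", inh = "#c62828")) +
    ggplot2::labs(x = "time (ms)", y = "rate (Hz)", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
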