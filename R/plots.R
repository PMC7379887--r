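#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a solved trajectory
#'
#' Premature and mature RNA abundance and the synthesis rate over time, one
#' facet per quantity (free y scales, since abundances and rates live on
#' different scales).
#'
#' @param object A `kinetic_trajectory` from [solve_kinetics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("premature", "mature", "synthesis"),
    names_to = "species", values_to = "value"
  )
  long$species <- factor(long$species, levels = c("premature", "mature", "synthesis"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an expression profile
#'
#' Observed means with +/- 1 sd error bars, one facet per species.
#'
#' @param object An [expression_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$species <- factor(df$species, levels = c("premature", "mature", "synthesis"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      size = 0.3, colour = "grey30"
    ) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "abundance / rate") +
    ggplot2::theme_minimal()
}

#' Plot a fit against its data
#'
#' Observed means (+/- 1 sd) with the fitted model's curves overlaid on a
#' dense time grid; one facet per observed species.
#'
#' @param object A `kinetic_fit` from [fit_kinetics()].
#' @param n_grid Number of points in the dense evaluation grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, n_grid = 200, ...) {
  prof <- as_tibble(object$data)
  rng <- range(prof$time)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  curves <- fitted_table(object, times = grid) |>
    dplyr::select("time", "species", "fitted_value")
  lv <- c("premature", "mature", "synthesis")
  prof$species <- factor(prof$species, levels = lv)
  curves$species <- factor(curves$species, levels = lv)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        y = .data$mean,
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
      ),
      size = 0.25, colour = "grey30"
    ) +
    ggplot2::geom_line(
      data = curves, ggplot2::aes(y = .data$fitted_value),
      colour = "#d7301f", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the kinetic rates of a model over time
#'
#' @param model A [kinetic_model()].
#' @param times Evaluation times (hours).
#' @return A ggplot object with one facet per rate.
#' @export
plot_rates <- function(model, times = seq(0, 16, length.out = 200)) {
  stopifnot(inherits(model, "kinetic_model"))
  df <- tibble(
    time = rep(times, 3),
    rate = rep(c("k1 synthesis", "k2 processing", "k3 degradation"),
      each = length(times)
    ),
    value = c(
      rate_eval(model$k1, times),
      rate_eval(model$k2, times),
      rate_eval(model$k3, times)
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#238b45", linewidth = 0.8) +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "rate") +
    ggplot2::theme_minimal()
}
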