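#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot state occupancy over the horizon
#'
#' Stacked-area plot of per-cycle health-state occupancy.
#'
#' @param object A [run_cohort()] trace.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- state_occupancy(object)
  df$state <- factor(df$state, levels = rev(model_states()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (years)", y = "Cohort fraction",
                  fill = "State",
                  title = paste(attr(object, "strategy"), "strategy")) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the outcome at the low and high perturbation
#' of each parameter, widest on top; the dashed line marks the base-case
#' outcome.
#'
#' @param object An `owsa_result` from [run_owsa()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df$low_result, df$high_result)
  df$hi <- pmax(df$low_result, df$high_result)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_result"),
                        linetype = "dashed") +
    ggplot2::labs(x = attr(object, "outcome"), y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Plot a digitized curve with fitted models
#'
#' @param curve A [digitized_curve()].
#' @param models Named list (or single) [parametric_survival()] models to
#'   overlay.
#' @param horizon Extrapolation horizon for the fitted curves (years).
#' @return A ggplot.
#' @export
plot_curve_fit <- function(curve, models, horizon = NULL) {
  if (inherits(models, "parametric_survival")) {
    models <- list(fitted = models)
  }
  horizon <- horizon %||% (max(curve$time_years) * 1.5)
  grid <- seq(0, horizon, length.out = 200)
  fitted <- dplyr::bind_rows(lapply(names(models), function(nm) {
    tibble::tibble(model = nm, time_years = grid,
                   survival_probability = survival_at(models[[nm]], grid))
  }))
  ggplot2::ggplot(fitted, ggplot2::aes(x = .data$time_years,
                                       y = .data$survival_probability)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_point(data = tibble::as_tibble(curve), colour = "black",
                        size = 0.8) +
    ggplot2::labs(x = "Years", y = "S(t)", colour = NULL) +
    ggplot2::theme_minimal()
}
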