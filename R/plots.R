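# ggplot2 views of scan tables, moment dynamics and simulations.

#' Contour view of a duration scan
#'
#' Filled-contour plot of one scanned quantity over the two mean stage
#' durations (log axes, minutes), for tables produced by
#' [steady_state_scan()] on a [duration_grid()].
#'
#' @param scan A tibble from [steady_state_scan()] containing `dur1_min` and
#'   `dur2_min` columns.
#' @param value Name of the column to contour (e.g. `"r_star"`, `"phi"`,
#'   `"eta2"`, `"m_star"`, `"r_v"`).
#' @return A ggplot object.
#' @export
plot_scan_contour <- function(scan, value = "r_star") {
  stopifnot(all(c("dur1_min", "dur2_min", value) %in% names(scan)))
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$dur1_min, y = .data$dur2_min,
                                     z = .data[[value]])) +
    ggplot2::geom_contour_filled() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean S1 duration (min)", y = "mean S2 duration (min)",
                  fill = value)
}

#' Stage-conditioned mean trajectories
#'
#' Plots `m1(t)`, `m2(t)` and the population mean `m(t)` from a
#' [moment_dynamics()] table, with the stationary values as reference lines
#' when `params` is supplied.
#'
#' @param dynamics A tibble from [moment_dynamics()].
#' @param params Optional [model_params()] to draw the stationary means.
#' @return A ggplot object.
#' @export
plot_moment_dynamics <- function(dynamics, params = NULL) {
  d <- dplyr::bind_rows(
    tibble(t = dynamics$t, value = dynamics$m1, series = "m1"),
    tibble(t = dynamics$t, value = dynamics$m2, series = "m2"),
    tibble(t = dynamics$t, value = dynamics$m, series = "m")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "mean mRNA count", colour = NULL)
  if (!is.null(params)) {
    sm <- stationary_means(params)
    p <- p + ggplot2::geom_hline(
      yintercept = c(sm$m1_star, sm$m2_star, sm$m_star), linetype = "dashed",
      colour = "grey50")
  }
  p
}

#' @export
autoplot.telecycle_ssa <- function(object, ...) {
  if (is.null(object$events)) {
    abort("simulate with record_events = TRUE to plot the trajectory")
  }
  ggplot2::ggplot(object$events, ggplot2::aes(x = .data$t, y = .data$mrna)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "mRNA copy number")
}
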