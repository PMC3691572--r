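#' Plot a starch trajectory
#'
#' @param object A `starch_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.starch_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_hr, y = .data$starch)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time after dawn (hr)",
                  y = expression(Starch ~ (mg ~ g^{-1} ~ FW))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot a measured time course with its SEM bars
#'
#' @param data Time course (replicate or summary form).
#' @param fit Optional `starch_fit`; its best-fit curve is overlaid.
#' @return A ggplot.
#' @export
plot_timecourse <- function(data, fit = NULL) {
  s <- summarize_timecourse(data)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$time_hr, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.3
    ) +
    ggplot2::labs(x = "Time after dawn (hr)",
                  y = expression(Starch ~ (mg ~ g^{-1} ~ FW))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(min(s$time_hr), max(s$time_hr), length.out = 200)
    curve <- tibble::tibble(
      time_hr = tt,
      mean = theta_curve(fit$theta, tt, fit$model, fit$t_onset, fit$t_day)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Plot the best-so-far loss trace of an annealing run
#'
#' @param fit A `starch_fit`.
#' @return A ggplot.
#' @export
plot_anneal_trace <- function(fit) {
  stopifnot(inherits(fit, "starch_fit"))
  tb <- tibble::tibble(accepted_move = seq_along(fit$trace),
                       best_loss = fit$trace)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$accepted_move,
                                   y = .data$best_loss)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Accepted move", y = "Best loss so far") +
    ggplot2::theme_minimal()
}
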