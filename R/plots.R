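#' Plot experiment outcomes by strategy
#'
#' Dot-and-interval plot of the trial means and 95% CIs for the TWW
#' percentage and the annual overspill count, by strategy.
#'
#' @param object A `clinic_experiment`.
#' @param metrics Character vector of metric names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clinic_experiment <- function(object,
                                       metrics = c(
                                         "tww_pct_overall",
                                         "overspill_appointments"
                                       ),
                                       ...) {
  if (is.null(object$summary)) {
    abort("Nothing to plot: the experiment has a single trial.")
  }
  dat <- object$summary %>% filter(.data$metric %in% metrics)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$strategy, y = .data$mean)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "trial mean (95% CI)",
      title = "Clinic outcomes by strategy"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the referral-queue trajectory of one trial
#'
#' Referral-queue length at each session start across the simulated horizon,
#' with the warm-up period shaded and the booking-rule threshold marked.
#' Useful for checking that the collection window starts from realistic
#' congestion.
#'
#' @param object A `clinic_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clinic_trial <- function(object, ...) {
  sess <- object$sessions %>%
    mutate(week_frac = .data$start_abs / MIN_PER_WEEK)
  warmup <- object$config$warmup_weeks
  ggplot2::ggplot(
    sess, ggplot2::aes(x = .data$week_frac, y = .data$queue_length)
  ) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = warmup, ymin = -Inf, ymax = Inf, alpha = 0.12
    ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = object$config$rule$threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "week", y = "referral queue at session start",
      title = "Queue trajectory (shaded: warm-up; dashed: booking threshold)"
    ) +
    ggplot2::theme_minimal()
}
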