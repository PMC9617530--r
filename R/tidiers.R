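#' Tidy a replicated experiment into a results table
#'
#' One row per strategy with the headline outcome columns of the clinic
#' results table: completions, mean time to clinic (weekdays), TWW
#' percentage and overspill count, each as `mean (95% CI)` components.
#'
#' @param x A `clinic_experiment`.
#' @param ... Unused.
#' @return A tibble with columns `strategy`, `metric`, `mean`, `ci_lo`,
#'   `ci_hi` restricted to the headline metrics; use `x$summary` for every
#'   metric.
#' @export
tidy.clinic_experiment <- function(x, ...) {
  if (is.null(x$summary)) {
    abort("No summary available: the experiment has a single trial.")
  }
  headline <- c(
    "completing_total", "completing_cancer", "completing_noncancer",
    "mean_ttc_weekdays_cancer", "mean_ttc_weekdays_noncancer",
    "tww_pct_cancer", "tww_pct_noncancer", "tww_pct_overall",
    "overspill_appointments"
  )
  x$summary %>%
    filter(.data$metric %in% headline) %>%
    as_tibble()
}

#' @rdname tidy.clinic_experiment
#' @export
glance.clinic_experiment <- function(x, ...) {
  tibble(
    n_strategies = length(x$strategies), n_trials = x$n_trials,
    seed = x$seed
  )
}

#' Tidy per-trial metrics of a single trial
#'
#' @param x A `clinic_trial`.
#' @param ... Unused.
#' @return [compute_trial_metrics()] in long form (`metric`, `value`).
#' @export
tidy.clinic_trial <- function(x, ...) {
  compute_trial_metrics(x) %>%
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "metric", values_to = "value"
    )
}

#' @rdname tidy.clinic_trial
#' @export
glance.clinic_trial <- function(x, ...) {
  tibble(
    seed = x$seed, n_arrivals = nrow(x$patients),
    n_sessions = nrow(x$sessions),
    warmup_weeks = x$config$warmup_weeks,
    collection_weeks = x$config$collection_weeks
  )
}

#' Export an experiment as results-table and per-trial CSV files
#'
#' @param x A `clinic_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `summary.csv` (one row per strategy
#'   and metric with mean and CI) and `trials.csv` (tidy per-trial metrics).
#' @export
write_experiment_csv <- function(x, dir) {
  stopifnot(inherits(x, "clinic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    trials = file.path(dir, "trials.csv")
  )
  write.csv(as_tibble(x$summary), paths[["summary"]],
    row.names = FALSE
  )
  long <- x$trials %>%
    tidyr::pivot_longer(
      -dplyr::all_of(c("strategy", "trial", "seed")),
      names_to = "metric", values_to = "value"
    )
  write.csv(long, paths[["trials"]], row.names = FALSE)
  invisible(paths)
}
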