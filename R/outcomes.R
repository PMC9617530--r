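#' Elapsed weekdays between two simulation times
#'
#' Counts the Mon-Fri calendar days elapsed between two simulation instants:
#' the number of weekdays in the half-open interval of calendar days
#' `(day(from), day(to)]`. Same calendar day gives 0; Friday to the following
#' Monday gives 1; any 14-calendar-day gap gives 10. The simulation clock
#' starts at 00:00 on a Monday.
#'
#' @param from,to Simulation times in minutes (`to >= from`), vectorised.
#' @return Integer vector of elapsed weekdays.
#' @examples
#' time_to_clinic_weekdays(0, 14 * 1440) # 10
#' @export
time_to_clinic_weekdays <- function(from, to) {
  if (any(to < from, na.rm = TRUE)) {
    abort("`to` must not precede `from`.")
  }
  d0 <- floor(from / MIN_PER_DAY)
  d1 <- floor(to / MIN_PER_DAY)
  # weekdays in days [0, d): full weeks contribute 5, the remainder
  # contributes its leading weekdays (day 0 is a Monday)
  wd_before <- function(d) 5 * (d %/% 7) + pmin(d %% 7, 5)
  as.integer(wd_before(d1 + 1) - wd_before(d0 + 1))
}

#' Two-week-wait target attainment
#'
#' `TRUE` when the first clinic attendance falls within fourteen calendar
#' days of the patient entering the two-week-wait pathway at their GP
#' presentation. Patients whose referral is delayed by a six-week return
#' therefore always miss the target; patients never referred or never seen
#' are excluded (`NA`).
#'
#' @param presentation_time GP presentation time, simulation minutes.
#' @param first_clinic_time First clinic attendance, minutes (`NA` if never
#'   attended).
#' @return Logical vector (`NA` where not applicable).
#' @examples
#' tww_met(0, 14 * 1440) # TRUE: day 14 is within the target
#' tww_met(0, 15 * 1440) # FALSE
#' @export
tww_met <- function(presentation_time, first_clinic_time) {
  gap <- floor(first_clinic_time / MIN_PER_DAY) -
    floor(presentation_time / MIN_PER_DAY)
  if (any(gap < 0, na.rm = TRUE)) {
    abort("attendance precedes presentation")
  }
  gap <= 14
}

#' Compute outcome metrics for one trial
#'
#' Reduces a simulated trial to the replication-level outcome measures,
#' restricted to the results-collection window (model exits and overspill
#' routings whose timestamps fall inside it; the warm-up period is
#' discarded). A patient "completes the model" when they exit during the
#' window: after finishing all clinic activities, after discharge at initial
#' assessment, or at GP presentation if never referred.
#'
#' @param trial A `clinic_trial` from [run_trial()].
#' @param window Optional `c(start, end)` in minutes; defaults to the
#'   configured collection window (after warm-up).
#' @return A one-row tibble: completion counts (total and by cancer status),
#'   mean time to clinic in weekdays by status, TWW percentages by status and
#'   overall, overspill appointment count, and referral-pattern fractions
#'   (percent referred overall/by status, percent delayed among cancer
#'   completions, percent delayed among referred non-cancer completions).
#' @export
compute_trial_metrics <- function(trial, window = NULL) {
  stopifnot(inherits(trial, "clinic_trial"))
  cfg <- trial$config
  if (is.null(window)) {
    window <- c(
      cfg$warmup_weeks * MIN_PER_WEEK,
      (cfg$warmup_weeks + cfg$collection_weeks) * MIN_PER_WEEK
    )
  }
  horizon_min <- (cfg$warmup_weeks + cfg$collection_weeks) * MIN_PER_WEEK
  if (window[1] < 0 || window[2] > horizon_min || window[1] >= window[2]) {
    abort("`window` must lie within the simulated horizon.")
  }
  p <- trial$patients
  comp <- !is.na(p$completion_time) &
    p$completion_time >= window[1] & p$completion_time < window[2]
  cp <- p[comp, ]
  att <- !is.na(cp$first_clinic_time)
  bc <- cp$has_cancer

  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  ttc <- time_to_clinic_weekdays(
    cp$gp_arrival_time[att], cp$first_clinic_time[att]
  )
  tww <- tww_met(cp$gp_arrival_time[att], cp$first_clinic_time[att])
  att_bc <- bc[att]

  referred <- cp$referral_kind != "none"
  delayed <- cp$referral_kind == "delayed"
  sess_in <- trial$sessions$start_abs >= window[1] &
    trial$sessions$start_abs < window[2]

  tibble(
    completing_total = sum(comp),
    completing_cancer = sum(bc),
    completing_noncancer = sum(!bc),
    attended_total = sum(att),
    mean_ttc_weekdays_cancer = mean_or_na(ttc[att_bc]),
    mean_ttc_weekdays_noncancer = mean_or_na(ttc[!att_bc]),
    tww_pct_cancer = 100 * mean_or_na(tww[att_bc]),
    tww_pct_noncancer = 100 * mean_or_na(tww[!att_bc]),
    tww_pct_overall = 100 * mean_or_na(tww),
    overspill_appointments = sum(trial$sessions$n_overspill[sess_in]),
    returns_admitted = sum(trial$sessions$n_returns_admitted[sess_in]),
    referred_pct_overall = 100 * mean(referred),
    referred_pct_cancer = 100 * mean_or_na(referred[bc]),
    referred_pct_noncancer = 100 * mean_or_na(referred[!bc]),
    delayed_pct_cancer = 100 * mean_or_na(delayed[bc]),
    delayed_pct_referred_noncancer =
      100 * mean_or_na(delayed[!bc][referred[!bc]])
  )
}

#' Summarise outcome metrics across trials
#'
#' Mean and two-sided 95% confidence interval for every metric across
#' replicated trials. Intervals are t-based by default (the normal
#' approximation is available for comparison).
#'
#' @param metrics A data frame of per-trial metrics, one row per trial
#'   (e.g. rows of [compute_trial_metrics()] bound together), optionally with
#'   grouping columns such as `strategy`.
#' @param level Confidence level.
#' @param method `"t"` (default) or `"normal"`.
#' @return A `clinic_summary` tibble in long form: `metric`, `n_trials`,
#'   `mean`, `ci_lo`, `ci_hi` (plus any grouping columns).
#' @examples
#' summarize_trials(data.frame(tww_pct_overall = c(60, 70)))
#' @export
summarize_trials <- function(metrics, level = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(metrics))
  grp <- intersect(c("strategy"), names(metrics))
  num <- setdiff(
    names(metrics)[vapply(metrics, is.numeric, logical(1))],
    c("trial", "seed")
  )
  check <- metrics %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(.n = dplyr::n(), .groups = "drop")
  if (any(check$.n < 2)) {
    abort("At least two trials are required to summarise.")
  }
  out <- metrics %>%
    tidyr::pivot_longer(dplyr::all_of(num),
      names_to = "metric", values_to = "value"
    ) %>%
    group_by(across(dplyr::all_of(c(grp, "metric")))) %>%
    summarise(
      n_trials = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(.data$n_trials),
      .groups = "drop"
    ) %>%
    mutate(
      crit = if (method == "t") {
        qt(1 - (1 - level) / 2, df = pmax(.data$n_trials - 1, 1))
      } else {
        stats::qnorm(1 - (1 - level) / 2)
      },
      ci_lo = .data$mean - .data$crit * .data$se,
      ci_hi = .data$mean + .data$crit * .data$se
    ) %>%
    mutate(metric = factor(.data$metric, levels = num)) %>%
    arrange(across(dplyr::all_of(grp)), .data$metric) %>%
    mutate(metric = as.character(.data$metric)) %>%
    select(-"crit", -"se")
  class(out) <- c("clinic_summary", class(out))
  out
}
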