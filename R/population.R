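#' Generate the symptomatic-patient arrival stream
#'
#' Arrivals of symptomatic patients at their GP are a homogeneous Poisson
#' process on continuous calendar time, parameterised by the expected annual
#' volume over a 52-week year. An alternative convention draws literal
#' exponential inter-arrival times (the audit-reported mean of 16.2778
#' minutes corresponds to an arrival window of about 55 hours per week) and
#' folds them into a weekly arrival window; both conventions give the same
#' weekly volume and booking dynamics, which is what the clinic outcomes
#' depend on.
#'
#' @param horizon_weeks Simulated horizon, weeks (> 0).
#' @param annual_volume Expected number of arrivals per 52-week year (> 0).
#' @param demand_multiplier Scales the arrival rate (e.g. 1.10 for a 10%
#'   demand increase). May be 0 (empty stream).
#' @param convention `"poisson"` (default): homogeneous process over the full
#'   week; `"interarrival"`: exponential gaps with mean
#'   `arrival_window / (annual_volume * demand_multiplier / 52)` folded into
#'   the first `arrival_window` minutes of each week.
#' @param arrival_window Weekly arrival-window width in minutes (only used by
#'   the `"interarrival"` convention).
#' @return Strictly increasing numeric vector of arrival times in simulation
#'   minutes (minute 0 = Monday 00:00 of week 1).
#' @examples
#' set.seed(1)
#' length(generate_arrivals(52)) # ~ 10,542
#' @export
generate_arrivals <- function(horizon_weeks, annual_volume = 10542,
                              demand_multiplier = 1,
                              convention = c("poisson", "interarrival"),
                              arrival_window = 16.2778 * 10542 / 52) {
  convention <- match.arg(convention)
  if (!is.numeric(horizon_weeks) || length(horizon_weeks) != 1L ||
    horizon_weeks <= 0) {
    abort("`horizon_weeks` must be a single positive number.")
  }
  if (!is.numeric(annual_volume) || annual_volume <= 0) {
    abort("`annual_volume` must be positive.")
  }
  if (demand_multiplier < 0) {
    abort("`demand_multiplier` must be non-negative.")
  }
  if (demand_multiplier == 0) {
    return(numeric(0))
  }
  weekly <- annual_volume * demand_multiplier / 52
  if (convention == "poisson") {
    total <- horizon_weeks * MIN_PER_WEEK
    n <- rpois(1, weekly * horizon_weeks)
    times <- sort(runif(n, 0, total))
  } else {
    stopifnot(arrival_window > 0, arrival_window <= MIN_PER_WEEK)
    mean_gap <- arrival_window / weekly
    # draw on "active" time, then fold into each week's arrival window
    n_guess <- ceiling(horizon_weeks * weekly * 1.35 + 50)
    active <- cumsum(rexp(n_guess, rate = 1 / mean_gap))
    while (active[length(active)] < horizon_weeks * arrival_window) {
      active <- c(active, active[length(active)] +
        cumsum(rexp(n_guess, rate = 1 / mean_gap)))
    }
    active <- active[active < horizon_weeks * arrival_window]
    week <- floor(active / arrival_window)
    times <- week * MIN_PER_WEEK + (active - week * arrival_window)
  }
  # de-duplicate pathological ties to keep times strictly increasing
  unique(times)
}

#' Assign cancer status
#'
#' Cancer status is an independent Bernoulli draw per patient at the clinic's
#' underlying prevalence among two-week-wait referrals.
#'
#' @param patients A data frame of patients (one row each).
#' @param prevalence Probability of breast cancer, in `[0, 1]`
#'   (default 4.76%).
#' @return `patients` with a logical `has_cancer` column, as a tibble.
#' @examples
#' set.seed(1)
#' mean(assign_cancer(tibble::tibble(id = 1:1e4))$has_cancer)
#' @export
assign_cancer <- function(patients, prevalence = 0.0476) {
  stopifnot(is.data.frame(patients))
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
    is.na(prevalence) || prevalence < 0 || prevalence > 1) {
    abort("`prevalence` must be a single probability in [0, 1].")
  }
  patients$has_cancer <- runif(nrow(patients)) < prevalence
  as_tibble(patients)
}

#' Generate a synthetic patient population
#'
#' Convenience wrapper chaining [generate_arrivals()], [assign_cancer()] and
#' [sample_clinic_pathway()]: the complete synthetic input for one simulated
#' trial before triage.
#'
#' @inheritParams generate_arrivals
#' @inheritParams assign_cancer
#' @param table A [pathway_table()].
#' @return A tibble with one row per patient: `id`, `gp_arrival_time`
#'   (minutes), `has_cancer`, `pathway_label`, `discharged_after_assessment`,
#'   `activity_seq`.
#' @examples
#' set.seed(1)
#' generate_patients(horizon_weeks = 1)
#' @export
generate_patients <- function(horizon_weeks, annual_volume = 10542,
                              demand_multiplier = 1, prevalence = 0.0476,
                              table = pathway_table(),
                              convention = c("poisson", "interarrival"),
                              arrival_window = 16.2778 * 10542 / 52) {
  arr <- generate_arrivals(horizon_weeks, annual_volume, demand_multiplier,
    convention = convention, arrival_window = arrival_window
  )
  tibble(id = seq_along(arr), gp_arrival_time = arr) %>%
    assign_cancer(prevalence = prevalence) %>%
    sample_clinic_pathway(table = table)
}
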