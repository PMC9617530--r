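#' Primary-care triage configuration
#'
#' Parameters of the primary-care stage. Under `"standard_care"` every
#' patient is referred immediately at GP presentation and all test fields are
#' ignored. Under `"pinpoint"` a blood-based risk test with the given
#' sensitivity/specificity classifies each patient; GPs refer high-risk
#' results immediately, may override a low-risk result (immediate referral
#' anyway), and non-referred patients may return with persisting symptoms
#' after `delay_weeks` and receive a delayed referral.
#'
#' @param arm `"standard_care"` or `"pinpoint"`.
#' @param sensitivity,specificity Test accuracy (probability a cancer is
#'   classed high-risk; probability a non-cancer is classed low-risk).
#' @param gp_override Probability a low-risk result is overruled by the GP
#'   (immediate referral despite the test).
#' @param delayed_return_cancer Probability that a non-referred patient *with*
#'   cancer returns for a delayed referral.
#' @param delayed_return_noncancer Same for patients without cancer.
#' @param delay_weeks Return delay, weeks (fixed, default 6).
#' @param test_turnaround_min Minutes between the GP presentation (blood
#'   draw) and the test-informed referral decision. The default of one week
#'   reflects laboratory turnaround for the multi-marker panel plus the GP
#'   acting on the result, and reproduces the audited referral-to-clinic
#'   interval of an uncongested clinic; ignored under standard care.
#' @return A `triage_config` list.
#' @seealso [scenario_standard_care()], [scenario_pinpoint_1()],
#'   [scenario_pinpoint_2()]
#' @export
triage_config <- function(arm = c("standard_care", "pinpoint"),
                          sensitivity = 0.98, specificity = 0.20,
                          gp_override = 0,
                          delayed_return_cancer = 1,
                          delayed_return_noncancer = 0,
                          delay_weeks = 6,
                          test_turnaround_min = 7 * 1440) {
  arm <- match.arg(arm)
  fracs <- c(
    sensitivity = sensitivity, specificity = specificity,
    gp_override = gp_override,
    delayed_return_cancer = delayed_return_cancer,
    delayed_return_noncancer = delayed_return_noncancer
  )
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    abort("All triage probabilities must lie in [0, 1].")
  }
  if (delay_weeks <= 0) abort("`delay_weeks` must be positive.")
  if (test_turnaround_min < 0) abort("`test_turnaround_min` must be >= 0.")
  structure(
    list(
      arm = arm, sensitivity = sensitivity, specificity = specificity,
      gp_override = gp_override,
      delayed_return_cancer = delayed_return_cancer,
      delayed_return_noncancer = delayed_return_noncancer,
      delay_weeks = delay_weeks, test_turnaround_min = test_turnaround_min
    ),
    class = "triage_config"
  )
}

#' Scenario presets for the triage stage
#'
#' `scenario_standard_care()`: no testing, everyone referred immediately.
#' `scenario_pinpoint_1()`: full GP adherence to the test; every non-referred
#' patient with cancer returns at six weeks; no non-cancer returns.
#' `scenario_pinpoint_2()`: GPs overrule 20% of low-risk results, and 10% of
#' the remaining non-referred patients without cancer also return at six
#' weeks (all remaining patients with cancer return).
#'
#' @return A [triage_config()].
#' @export
scenario_standard_care <- function() triage_config("standard_care")

#' @rdname scenario_standard_care
#' @export
scenario_pinpoint_1 <- function() {
  triage_config("pinpoint",
    gp_override = 0,
    delayed_return_cancer = 1, delayed_return_noncancer = 0
  )
}

#' @rdname scenario_standard_care
#' @export
scenario_pinpoint_2 <- function() {
  triage_config("pinpoint",
    gp_override = 0.20,
    delayed_return_cancer = 1, delayed_return_noncancer = 0.10
  )
}

#' Apply the risk test
#'
#' Classifies each patient as high- or low-risk: a patient with cancer tests
#' high-risk with probability `sensitivity`; a patient without cancer tests
#' low-risk with probability `specificity`. Only valid for the `"pinpoint"`
#' arm.
#'
#' @param patients Data frame with a logical `has_cancer` column.
#' @param config A [triage_config()] with `arm = "pinpoint"`.
#' @return `patients` with a `risk_result` column
#'   (`"low"`/`"high"`), as a tibble.
#' @export
apply_test <- function(patients, config) {
  stopifnot(is.data.frame(patients), "has_cancer" %in% names(patients))
  stopifnot(inherits(config, "triage_config"))
  if (config$arm != "pinpoint") {
    abort("`apply_test()` is only defined for the pinpoint arm.")
  }
  u <- runif(nrow(patients))
  patients$risk_result <- if_else(
    patients$has_cancer,
    if_else(u < config$sensitivity, "high", "low"),
    if_else(u < config$specificity, "low", "high")
  )
  as_tibble(patients)
}

#' Decide referral kind and timing
#'
#' Standard care refers every patient immediately. In the pinpoint arm,
#' high-risk results are referred immediately; low-risk results are first
#' subject to an independent GP override (immediate referral); patients left
#' non-referred may return with persisting symptoms after the fixed delay and
#' receive a delayed referral (probability by cancer status); the remainder
#' are never referred.
#'
#' @param patients Data frame with `has_cancer`, `gp_arrival_time`, and (for
#'   the pinpoint arm) `risk_result` columns.
#' @param config A [triage_config()].
#' @return `patients` with columns `referral_kind`
#'   (`"immediate"`/`"delayed"`/`"none"`), `risk_result` (`"not_tested"`
#'   under standard care) and `referral_time` (simulation minutes; `NA` if
#'   never referred), as a tibble.
#' @examples
#' set.seed(1)
#' pats <- assign_cancer(tibble::tibble(id = 1:6, gp_arrival_time = 0))
#' decide_referral(apply_test(pats, scenario_pinpoint_2()),
#'   scenario_pinpoint_2()
#' )
#' @export
decide_referral <- function(patients, config) {
  stopifnot(
    is.data.frame(patients),
    all(c("has_cancer", "gp_arrival_time") %in% names(patients))
  )
  stopifnot(inherits(config, "triage_config"))
  n <- nrow(patients)
  base <- patients$gp_arrival_time + config$test_turnaround_min
  if (config$arm == "standard_care") {
    patients$risk_result <- rep("not_tested", n)
    patients$referral_kind <- rep("immediate", n)
    patients$referral_time <- patients$gp_arrival_time
    return(as_tibble(patients))
  }
  if (!("risk_result" %in% names(patients))) {
    abort("pinpoint arm requires a `risk_result` column; run `apply_test()`.")
  }
  kind <- rep("none", n)
  kind[patients$risk_result == "high"] <- "immediate"
  low <- which(patients$risk_result == "low")
  if (length(low)) {
    override <- runif(length(low)) < config$gp_override
    kind[low[override]] <- "immediate"
    rest <- low[!override]
    if (length(rest)) {
      p_ret <- if_else(patients$has_cancer[rest],
        config$delayed_return_cancer, config$delayed_return_noncancer
      )
      returns <- runif(length(rest)) < p_ret
      kind[rest[returns]] <- "delayed"
    }
  }
  patients$referral_kind <- kind
  patients$referral_time <- dplyr::case_when(
    kind == "immediate" ~ base,
    kind == "delayed" ~ base + config$delay_weeks * MIN_PER_WEEK,
    TRUE ~ NA_real_
  )
  as_tibble(patients)
}

#' Closed-form referral fractions
#'
#' Analytic expectations of the referral pattern implied by a triage
#' configuration, used as the independent oracle for the simulated
#' fractions. For a patient without cancer the referral probability is
#' `(1 - spec) + spec * ov + spec * (1 - ov) * d_nc` (false-positive, GP
#' override, delayed return); for a patient with cancer it is
#' `sens + (1 - sens) * ov + (1 - sens) * (1 - ov) * d_c`.
#'
#' @param config A [triage_config()].
#' @param prevalence Cancer prevalence used for the overall mix.
#' @return A one-row tibble: `referred_overall`, `referred_cancer`,
#'   `referred_noncancer`, `delayed_among_referred_cancer`,
#'   `delayed_among_referred_noncancer`, `delayed_among_cancer` (all
#'   fractions).
#' @examples
#' referral_fraction_closed_form(scenario_pinpoint_2())
#' @export
referral_fraction_closed_form <- function(config, prevalence = 0.0476) {
  stopifnot(inherits(config, "triage_config"))
  if (config$arm == "standard_care") {
    return(tibble(
      referred_overall = 1, referred_cancer = 1, referred_noncancer = 1,
      delayed_among_referred_cancer = 0, delayed_among_referred_noncancer = 0,
      delayed_among_cancer = 0
    ))
  }
  sens <- config$sensitivity
  spec <- config$specificity
  ov <- config$gp_override
  d_c <- config$delayed_return_cancer
  d_nc <- config$delayed_return_noncancer
  del_nc <- spec * (1 - ov) * d_nc
  del_c <- (1 - sens) * (1 - ov) * d_c
  ref_nc <- (1 - spec) + spec * ov + del_nc
  ref_c <- sens + (1 - sens) * ov + del_c
  tibble(
    referred_overall = prevalence * ref_c + (1 - prevalence) * ref_nc,
    referred_cancer = ref_c,
    referred_noncancer = ref_nc,
    delayed_among_referred_cancer = del_c / ref_c,
    delayed_among_referred_noncancer = del_nc / ref_nc,
    delayed_among_cancer = del_c
  )
}

#' Run the triage stage on a patient population
#'
#' Applies the risk test (pinpoint arm only) and the referral decision in one
#' step.
#'
#' @inheritParams decide_referral
#' @return `patients` with `risk_result`, `referral_kind`, `referral_time`.
#' @export
triage_patients <- function(patients, config) {
  stopifnot(inherits(config, "triage_config"))
  if (config$arm == "pinpoint") {
    patients <- apply_test(patients, config)
  }
  decide_referral(patients, config)
}
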