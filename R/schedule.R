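SESSION_NAMES <- c(
  "mon_am", "tue_am", "tue_pm", "wed_am", "wed_pm",
  "thu_am", "thu_pm", "fri_am"
)

#' Weekly clinic session schedule
#'
#' The clinic runs seven weekly "full" sessions (Mon AM, Tue PM, Wed AM/PM,
#' Thu AM/PM, Fri AM) plus one reduced-capacity "add-on" session (Tue AM).
#' All sessions last four hours (AM 09:00-13:00, PM 14:00-18:00) with a
#' 15-minute staff overtime allowance. Full sessions book 25 new patients by
#' default (expandable under the queue-responsive rule, see
#' [plan_session_capacity()]) and reserve 5 slots for overspill returns; the
#' add-on session books 10 new patients and reserves 6 return slots.
#'
#' @param disable Character vector of session names to remove (service
#'   reconfiguration), a subset of
#'   `c("mon_am","tue_am","tue_pm","wed_am","wed_pm","thu_am","thu_pm","fri_am")`.
#' @return A tibble with one row per enabled weekly session, in chronological
#'   order: `session`, `day` (0 = Monday), `period`, `kind`
#'   (`"full"`/`"add_on"`), `start_min`/`close_min` (minutes from Monday
#'   00:00), `overtime_min`, `base_new_slots`, `max_new_slots`,
#'   `overspill_slots`.
#' @examples
#' clinic_schedule()
#' clinic_schedule(disable = "tue_am")
#' @export
clinic_schedule <- function(disable = character()) {
  if (length(disable)) {
    bad <- setdiff(disable, SESSION_NAMES)
    if (length(bad)) {
      abort(paste0(
        "Unknown session name(s): ", paste(bad, collapse = ", "),
        ". Valid names: ", paste(SESSION_NAMES, collapse = ", ")
      ))
    }
  }
  sched <- tibble(
    session = SESSION_NAMES,
    day = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L),
    period = c("am", "am", "pm", "am", "pm", "am", "pm", "am"),
    kind = c(
      "full", "add_on", "full", "full", "full", "full", "full", "full"
    )
  ) %>%
    mutate(
      start_min = .data$day * MIN_PER_DAY +
        if_else(.data$period == "am", 9L, 14L) * 60L,
      close_min = .data$start_min + 240L,
      overtime_min = 15L,
      base_new_slots = if_else(.data$kind == "full", 25L, 10L),
      max_new_slots = if_else(.data$kind == "full", 34L, 10L),
      overspill_slots = if_else(.data$kind == "full", 5L, 6L)
    ) %>%
    filter(!(.data$session %in% disable)) %>%
    arrange(.data$start_min)
  sched
}

#' Queue-responsive booking rule
#'
#' Full clinics book `base` new patients by default; above a referral queue
#' of `threshold` the booking for the next full clinic grows by one patient
#' per additional `step` patients in the queue, capped at `max`. Add-on
#' clinics always book their fixed number.
#'
#' @param threshold Queue length above which full-clinic bookings expand.
#' @param step Queue increment per additional booked patient.
#' @param max Maximum new patients per full clinic.
#' @param include_returns Count the overspill returns admitted to the
#'   session as part of the clinic queue when planning its capacity? The
#'   default reads the "clinic queue" as the session's total pending load —
#'   waiting new referrals plus the returns it will see — since the rule
#'   models the clinic's responsiveness to overall workload pressure; set
#'   `FALSE` to count the new-referral queue only.
#' @param rounding How a part-completed step of `step` extra patients maps to
#'   bookings: `"floor"` (default) adds the extra slot only once the full
#'   step of `step` additional patients is exceeded; `"nearest"` once the
#'   queue is more than half a step in; `"ceiling"` as soon as the step
#'   begins.
#' @return A `booking_rule` list.
#' @export
booking_rule <- function(threshold = 380, step = 15, max = 34,
                         include_returns = TRUE,
                         rounding = c("floor", "nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(threshold >= 0, step > 0, max > 0, is.logical(include_returns))
  structure(
    list(
      threshold = threshold, step = step, max = max,
      include_returns = include_returns, rounding = rounding
    ),
    class = "booking_rule"
  )
}

#' Plan new-patient capacity for a session
#'
#' @param kind `"full"` or `"add_on"`.
#' @param queue_length Referral-queue length at the session start instant.
#' @param base_new_slots Default bookings for this session.
#' @param rule A [booking_rule()] (applies to full sessions only).
#' @return Integer number of new-patient slots.
#' @examples
#' plan_session_capacity("full", 380) # 25: the rule engages only above 380
#' plan_session_capacity("full", 395) # 26
#' plan_session_capacity("full", 1e4) # 34
#' @export
plan_session_capacity <- function(kind, queue_length, base_new_slots = NULL,
                                  rule = booking_rule()) {
  stopifnot(queue_length >= 0)
  if (kind == "add_on") {
    return(as.integer(base_new_slots %||% 10L))
  }
  base <- as.integer(base_new_slots %||% 25L)
  round_fn <- switch(rule$rounding %||% "floor",
    floor = floor,
    ceiling = ceiling,
    nearest = function(x) floor(x + 0.5)
  )
  extra <- round_fn(max(0, queue_length - rule$threshold) / rule$step)
  as.integer(min(base + extra, rule$max))
}

#' Clinic room counts
#'
#' One room (with its device where relevant) per concurrent activity.
#'
#' @param initial_assessment,mammogram,ultrasound,biopsy Room counts.
#' @return Named integer vector.
#' @export
clinic_rooms <- function(initial_assessment = 4, mammogram = 3,
                         ultrasound = 4, biopsy = 4) {
  rooms <- c(
    initial_assessment = as.integer(initial_assessment),
    mammogram = as.integer(mammogram),
    ultrasound = as.integer(ultrasound),
    biopsy = as.integer(biopsy)
  )
  if (any(rooms < 0)) abort("Room counts must be non-negative.")
  rooms
}

#' Per-session staff roster
#'
#' Staff headcounts by role for one clinic session, with a per-role
#' availability fraction (share of the shift not lost to administrative and
#' follow-up work). Availability is modelled as thinned capacity: after each
#' task of length `d` a staff member is engaged on other duties for
#' `d * (1 - a) / a` minutes, so each role supplies `count * a` effective
#' servers in the long run.
#'
#' The shipped default full-session roster, with its availability value, was
#' calibrated so that the standard-care arm reproduces the annual number of
#' overspill appointments recorded in the clinic audit (about 1,664); the
#' add-on session runs a half roster (rounded up).
#'
#' @param consultant,nurse_practitioner,physician_associate,band7_sonographer,band6_sonographer,band6_non_sonographer,grade2_assistant
#'   Headcounts present during the session.
#' @param availability Availability fraction(s) in (0, 1]: a single number or
#'   a vector named by role.
#' @return A `clinic_roster` list with `counts` (named integer) and
#'   `availability` (named numeric).
#' @export
clinic_roster <- function(consultant = 2, nurse_practitioner = 1,
                          physician_associate = 1, band7_sonographer = 2,
                          band6_sonographer = 1, band6_non_sonographer = 1,
                          grade2_assistant = 2, availability = 0.672) {
  counts <- c(
    consultant = consultant, nurse_practitioner = nurse_practitioner,
    physician_associate = physician_associate,
    band7_sonographer = band7_sonographer,
    band6_sonographer = band6_sonographer,
    band6_non_sonographer = band6_non_sonographer,
    grade2_assistant = grade2_assistant
  )
  counts <- setNames(as.integer(counts), ROLE_LEVELS)
  if (any(counts < 0)) abort("Staff counts must be non-negative.")
  if (length(availability) == 1L && is.null(names(availability))) {
    avail <- setNames(rep(as.numeric(availability), 7L), ROLE_LEVELS)
  } else {
    avail <- setNames(rep(1, 7L), ROLE_LEVELS)
    bad <- setdiff(names(availability), ROLE_LEVELS)
    if (length(bad)) {
      abort(paste0("Unknown role(s): ", paste(bad, collapse = ", ")))
    }
    avail[names(availability)] <- as.numeric(availability)
  }
  if (any(avail <= 0) || any(avail > 1)) {
    abort("Availability fractions must lie in (0, 1].")
  }
  structure(list(counts = counts, availability = avail),
    class = "clinic_roster"
  )
}

#' Half-strength add-on roster
#'
#' @param full A [clinic_roster()] for a full session.
#' @return A `clinic_roster` with headcounts halved (rounded up).
#' @export
addon_roster <- function(full = clinic_roster()) {
  stopifnot(inherits(full, "clinic_roster"))
  clinic_roster(
    consultant = ceiling(full$counts[["consultant"]] / 2),
    nurse_practitioner = ceiling(full$counts[["nurse_practitioner"]] / 2),
    physician_associate = ceiling(full$counts[["physician_associate"]] / 2),
    band7_sonographer = ceiling(full$counts[["band7_sonographer"]] / 2),
    band6_sonographer = ceiling(full$counts[["band6_sonographer"]] / 2),
    band6_non_sonographer =
      ceiling(full$counts[["band6_non_sonographer"]] / 2),
    grade2_assistant = ceiling(full$counts[["grade2_assistant"]] / 2),
    availability = full$availability
  )
}

#' Full simulation configuration
#'
#' Bundles every model input for one strategy arm: demand, prevalence,
#' diagnostic pathway mix, triage rules, weekly schedule, booking rule,
#' rooms, rosters, activity durations, and horizon.
#'
#' @param triage A [triage_config()].
#' @param disable_sessions Session names removed from the weekly schedule
#'   (service reconfiguration).
#' @param annual_volume Expected GP arrivals per 52-week year.
#' @param demand_multiplier Arrival-rate multiplier.
#' @param prevalence Cancer prevalence.
#' @param pathway A [pathway_table()].
#' @param durations A [duration_model()].
#' @param rule A [booking_rule()].
#' @param rooms A [clinic_rooms()] vector.
#' @param roster_full,roster_addon [clinic_roster()]s for full and add-on
#'   sessions.
#' @param warmup_weeks,collection_weeks Warm-up (discarded) and results
#'   collection horizon, weeks.
#' @param booking_notice_days Minimum notice between a referral and the
#'   clinic session it can be booked into (appointment-letter lead time),
#'   calendar days (default 0: a waiting patient can be booked into the next
#'   session). Patients referred less than this long before a session start
#'   wait for a later session; they still count in the clinic queue that
#'   drives the capacity rule.
#' @param appointment_spread_min Width, in minutes from session start, of
#'   the window over which booked patients' appointment times are spread
#'   (evenly spaced, overspill returns first). `0` puts every booked patient
#'   at the session start; the default staggers appointments across the
#'   first three hours of the four-hour session, as clinics do in practice,
#'   so that late-appointment patients with long diagnostic sequences can
#'   overspill even in an uncongested clinic.
#' @param arrival_convention Passed to [generate_arrivals()].
#' @return A `clinic_config` list.
#' @examples
#' cfg <- clinic_config(scenario_pinpoint_2(), disable_sessions = "tue_am")
#' @export
clinic_config <- function(triage = scenario_standard_care(),
                          disable_sessions = character(),
                          annual_volume = 10542,
                          demand_multiplier = 1,
                          prevalence = 0.0476,
                          pathway = pathway_table(),
                          durations = duration_model(),
                          rule = booking_rule(),
                          rooms = clinic_rooms(),
                          roster_full = clinic_roster(),
                          roster_addon = addon_roster(roster_full),
                          warmup_weeks = 12,
                          collection_weeks = 52,
                          booking_notice_days = 0,
                          appointment_spread_min = 190,
                          arrival_convention = "poisson") {
  cfg <- structure(
    list(
      triage = triage, disable_sessions = disable_sessions,
      annual_volume = annual_volume, demand_multiplier = demand_multiplier,
      prevalence = prevalence, pathway = pathway, durations = durations,
      rule = rule, rooms = rooms, roster_full = roster_full,
      roster_addon = roster_addon, warmup_weeks = warmup_weeks,
      collection_weeks = collection_weeks,
      booking_notice_days = booking_notice_days,
      appointment_spread_min = appointment_spread_min,
      arrival_convention = arrival_convention
    ),
    class = "clinic_config"
  )
  validate_clinic_config(cfg)
  cfg
}

# staff roles able to perform each activity / stage (engine preference order)
.eligible_roles <- list(
  initial_assessment = c(
    "nurse_practitioner", "physician_associate", "consultant"
  ),
  mammogram = c(
    "band6_non_sonographer", "band6_sonographer", "band7_sonographer"
  ),
  ultrasound = c("band6_sonographer", "band7_sonographer"),
  biopsy_lead = "consultant",
  biopsy_assist = c(
    "grade2_assistant", "band6_non_sonographer", "band6_sonographer"
  ),
  prep = c(
    "grade2_assistant", "band6_non_sonographer", "band6_sonographer"
  )
)

#' Validate a simulation configuration
#'
#' Checks structural coherence before any simulation runs, including the
#' staffing deadlock condition: every clinic activity must have at least one
#' eligible staff member rostered in every enabled session kind, otherwise
#' patients needing that activity could never be served.
#'
#' @param config A [clinic_config()].
#' @return `config`, invisibly; errors describe the first problem found.
#' @export
validate_clinic_config <- function(config) {
  if (!inherits(config, "clinic_config")) {
    abort("`config` must be a `clinic_config`.")
  }
  stopifnot(
    inherits(config$triage, "triage_config"),
    inherits(config$pathway, "clinic_pathway_table"),
    inherits(config$durations, "clinic_duration_model"),
    inherits(config$rule, "booking_rule"),
    inherits(config$roster_full, "clinic_roster"),
    inherits(config$roster_addon, "clinic_roster")
  )
  if (config$annual_volume <= 0) abort("`annual_volume` must be positive.")
  if (config$demand_multiplier < 0) {
    abort("`demand_multiplier` must be non-negative.")
  }
  if (config$prevalence < 0 || config$prevalence > 1) {
    abort("`prevalence` must be a probability.")
  }
  if (config$warmup_weeks < 0 || config$collection_weeks <= 0) {
    abort("Horizon weeks invalid.")
  }
  if ((config$booking_notice_days %||% 0) < 0) {
    abort("`booking_notice_days` must be non-negative.")
  }
  spread <- config$appointment_spread_min %||% 0
  if (spread < 0 || spread >= 240) {
    abort("`appointment_spread_min` must lie in [0, 240).")
  }
  sched <- clinic_schedule(config$disable_sessions) # validates names
  if (length(config$rooms) != 4L || any(config$rooms < 0)) {
    abort("`rooms` must be the four activity room counts.")
  }
  kinds <- unique(sched$kind)
  for (kind in kinds) {
    roster <- if (kind == "full") config$roster_full else config$roster_addon
    for (stage in names(.eligible_roles)) {
      if (sum(roster$counts[.eligible_roles[[stage]]]) == 0L) {
        abort(paste0(
          "Staffing deadlock: no eligible staff for `", stage,
          "` in ", kind, " sessions."
        ))
      }
    }
  }
  invisible(config)
}
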