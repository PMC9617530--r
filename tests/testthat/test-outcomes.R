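DAY <- 1440

test_that("weekday counting follows the calendar", {
  expect_equal(time_to_clinic_weekdays(0, 0), 0L) # same Monday
  expect_equal(time_to_clinic_weekdays(100, 600), 0L) # same calendar day
  # Friday (day 4) to the following Monday (day 7): one weekday elapses
  expect_equal(time_to_clinic_weekdays(4 * DAY, 7 * DAY), 1L)
  # any 14-calendar-day gap spans exactly ten weekdays
  for (d0 in 0:6) {
    expect_equal(
      time_to_clinic_weekdays(d0 * DAY, (d0 + 14) * DAY), 10L
    )
  }
  # Monday to Friday same week: four weekdays
  expect_equal(time_to_clinic_weekdays(0, 4 * DAY), 4L)
  # Saturday to Sunday: none
  expect_equal(time_to_clinic_weekdays(5 * DAY, 6 * DAY), 0L)
  expect_error(time_to_clinic_weekdays(10 * DAY, 0), "precede")
})

test_that("TWW boundary sits at fourteen calendar days", {
  expect_true(tww_met(0, 14 * DAY))
  expect_true(tww_met(0, 14 * DAY + 1439))
  expect_false(tww_met(0, 15 * DAY))
  expect_true(is.na(tww_met(0, NA)))
  # a six-week delayed return can never meet the target from presentation
  expect_false(tww_met(0, 42 * DAY))
})

test_that("trial metrics reduce a constructed log correctly", {
  # four attended patients, two meeting the target; one never referred
  patients <- tibble::tibble(
    id = 1:5,
    gp_arrival_time = c(0, 0, 0, 0, 0),
    has_cancer = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    referral_kind = c("immediate", "immediate", "immediate", "delayed",
      "none"),
    referral_time = c(0, 0, 0, 42 * DAY, NA),
    first_clinic_time = c(10 * DAY, 13 * DAY, 16 * DAY, 50 * DAY, NA),
    completion_time = c(10 * DAY, 13 * DAY, 16 * DAY, 50 * DAY, 0),
    overspill_events = c(0L, 0L, 0L, 0L, 0L),
    booked = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  sessions <- tibble::tibble(
    week = 1L, session = "mon_am", kind = "full", start_abs = 540,
    base_new_slots = 25L, overspill_slots = 5L, queue_length = 0L,
    returns_backlog = 0L, planned_capacity = 25L, n_new_booked = 4L,
    n_returns_admitted = 0L, n_overspill = 0L
  )
  trial <- structure(
    list(
      patients = patients, sessions = sessions,
      config = clinic_config(warmup_weeks = 0, collection_weeks = 9),
      seed = 1
    ),
    class = "clinic_trial"
  )
  m <- compute_trial_metrics(trial)
  expect_equal(m$completing_total, 5L)
  expect_equal(m$attended_total, 4L)
  expect_equal(m$tww_pct_overall, 50) # 10 and 13 days met; 16 and 50 missed
  expect_equal(m$tww_pct_cancer, 100)
  expect_equal(m$overspill_appointments, 0L)
  expect_equal(m$referred_pct_overall, 80)
  expect_equal(m$delayed_pct_referred_noncancer, 100 * 1 / 3)
  expect_error(
    compute_trial_metrics(trial, window = c(0, 1e9)), "horizon"
  )
})

test_that("overall TWW is the attendance-weighted mix of the strata", {
  tr <- run_trial(quick_config(scenario_pinpoint_2()), seed = 31)
  m <- compute_trial_metrics(tr)
  p <- tr$patients
  w <- c(
    cfg <- tr$config$warmup_weeks * 7 * DAY,
    (tr$config$warmup_weeks + tr$config$collection_weeks) * 7 * DAY
  )
  comp <- !is.na(p$completion_time) &
    p$completion_time >= w[1] & p$completion_time < w[2]
  att <- comp & !is.na(p$first_clinic_time)
  n_bc <- sum(att & p$has_cancer)
  n_nbc <- sum(att & !p$has_cancer)
  mix <- (m$tww_pct_cancer * n_bc + m$tww_pct_noncancer * n_nbc) /
    (n_bc + n_nbc)
  expect_equal(m$tww_pct_overall, mix, tolerance = 1e-10)
})

test_that("trial summaries give exact t-intervals", {
  s <- summarize_trials(data.frame(tww_pct_overall = c(60, 70)))
  row <- s[s$metric == "tww_pct_overall", ]
  expect_equal(row$mean, 65)
  half <- qt(0.975, df = 1) * sd(c(60, 70)) / sqrt(2)
  expect_equal(row$ci_hi - row$mean, half)
  expect_equal(row$mean - row$ci_lo, half)

  same <- summarize_trials(data.frame(x = rep(42, 150)))
  expect_equal(same$ci_lo, same$ci_hi)
  expect_equal(same$mean, 42)

  expect_error(summarize_trials(data.frame(x = 1)), "two trials")

  norm <- summarize_trials(
    data.frame(x = c(60, 70)),
    method = "normal"
  )
  expect_lt(norm$ci_hi, row$ci_hi) # z-interval narrower than t at n = 2
})

test_that("95% intervals cover a known mean about 95% of the time", {
  set.seed(301)
  covered <- replicate(400, {
    x <- rnorm(12, mean = 50, sd = 5)
    s <- summarize_trials(data.frame(metric_x = x))
    s$ci_lo <= 50 && 50 <= s$ci_hi
  })
  # binomial band around 0.95 with 400 meta-replications
  expect_within_binomial_band(mean(covered), 0.95, 400, k = 3.3)
})
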