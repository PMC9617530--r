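test_that("weekly schedule holds eight sessions with the stated capacity", {
  sched <- clinic_schedule()
  expect_equal(nrow(sched), 8)
  expect_equal(sum(sched$kind == "full"), 7)
  expect_equal(sum(sched$base_new_slots), 7 * 25 + 10) # 185 new/week
  expect_equal(sum(sched$overspill_slots), 7 * 5 + 6)
  expect_true(all(diff(sched$start_min) > 0))
  expect_true(all(sched$close_min - sched$start_min == 240))

  expect_equal(nrow(clinic_schedule(disable = "tue_am")), 7)
  expect_equal(nrow(clinic_schedule(disable = c("tue_am", "wed_am"))), 6)
  expect_equal(nrow(clinic_schedule(disable = SESSION_NAMES <- c(
    "mon_am", "tue_am", "tue_pm", "wed_am", "wed_pm", "thu_am", "thu_pm",
    "fri_am"
  ))), 0)
  expect_error(clinic_schedule(disable = "sat_am"), "Unknown session")
})

test_that("queue-responsive capacity follows the 380/15/34 rule", {
  expect_equal(plan_session_capacity("full", 0), 25L)
  expect_equal(plan_session_capacity("full", 380), 25L)
  expect_equal(plan_session_capacity("full", 395), 26L)
  expect_equal(plan_session_capacity("full", 515), 34L)
  expect_equal(plan_session_capacity("full", 10000), 34L)
  expect_equal(plan_session_capacity("add_on", 10000), 10L)
  expect_equal(plan_session_capacity("add_on", 0), 10L)

  # rounding conventions differ only inside a part-completed step
  fl <- booking_rule(rounding = "floor")
  ce <- booking_rule(rounding = "ceiling")
  ne <- booking_rule(rounding = "nearest")
  expect_equal(plan_session_capacity("full", 381, rule = fl), 25L)
  expect_equal(plan_session_capacity("full", 381, rule = ce), 26L)
  expect_equal(plan_session_capacity("full", 381, rule = ne), 25L)
  expect_equal(plan_session_capacity("full", 389, rule = ne), 26L)
  expect_equal(plan_session_capacity("full", 395, rule = ce), 26L)
})

test_that("session booking is FIFO with reserved, non-convertible returns", {
  bk <- book_session(100, 0, kind = "full")
  expect_equal(bk$n_new, 25L)
  bk2 <- book_session(100, 2, kind = "full")
  expect_equal(bk2$n_returns, 2L) # three reserve slots stay unused
  expect_equal(bk2$n_new, 25L) # and are not converted to new slots
  bk3 <- book_session(0, 20, kind = "full")
  expect_equal(bk3$n_new, 0L)
  expect_equal(bk3$n_returns, 5L)
  bk4 <- book_session(0, 20, kind = "add_on")
  expect_equal(bk4$n_returns, 6L)
  # booking notice: only aged referrals are bookable
  bk5 <- book_session(400, 0, kind = "full", bookable = 3)
  expect_equal(bk5$n_new, 3L)
  expect_gt(bk5$planned_capacity, 25L)
})

test_that("roster construction, halving and availability validate", {
  r <- clinic_roster()
  expect_equal(unname(r$counts), c(2L, 1L, 1L, 2L, 1L, 1L, 2L))
  a <- addon_roster(r)
  expect_equal(unname(a$counts), c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_error(clinic_roster(availability = 0), "\\(0, 1\\]")
  expect_error(clinic_roster(consultant = -1))
  r2 <- clinic_roster(availability = c(consultant = 0.5))
  expect_equal(unname(r2$availability[["consultant"]]), 0.5)
  expect_equal(unname(r2$availability[["grade2_assistant"]]), 1)
})

test_that("configs with an unstaffable activity are rejected up front", {
  # no consultant anywhere: biopsy can never run
  bad <- clinic_roster(
    consultant = 0, nurse_practitioner = 1, physician_associate = 1,
    band7_sonographer = 1, band6_sonographer = 1, band6_non_sonographer = 1,
    grade2_assistant = 1
  )
  expect_error(
    clinic_config(roster_full = bad, roster_addon = bad),
    "deadlock"
  )
  # no sonographer: ultrasound can never run
  bad2 <- clinic_roster(band7_sonographer = 0, band6_sonographer = 0)
  expect_error(
    clinic_config(roster_full = bad2, roster_addon = bad2),
    "deadlock"
  )
  expect_silent(validate_clinic_config(clinic_config()))
})

test_that("config fixtures round-trip through YAML", {
  cfg <- clinic_config(
    scenario_pinpoint_2(),
    disable_sessions = "tue_am", demand_multiplier = 1.1
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_clinic_config(cfg, path)
  back <- read_clinic_config(path)
  expect_equal(back$triage$gp_override, 0.20)
  expect_equal(back$disable_sessions, "tue_am")
  expect_equal(back$demand_multiplier, 1.1)
  expect_equal(back$pathway$p_cancer, cfg$pathway$p_cancer)
  expect_equal(back$roster_full$availability, cfg$roster_full$availability)

  # shipped presets load and validate
  for (f in c("standard_care.yaml", "scenario1.yaml", "scenario2.yaml")) {
    expect_s3_class(
      read_clinic_config(clinicflow_example(f)), "clinic_config"
    )
  }
})
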