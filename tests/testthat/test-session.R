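# Hand-simulated micro instances are the exact oracle for the session
# engine: with zero duration dispersion every start and end time is known.

test_that("engine reproduces the hand-simulated two-patient schedule", {
  pats <- tibble::tibble(activity_seq = list(c(1L, 3L), c(1L, 3L)))
  dm <- duration_model(dispersion = 0, prep = 5)

  # one consultant, one sonographer, one assistant:
  # P1 assess 0-10, prep 10-15, US 15-35; P2 assess 10-20 (consultant
  # freed), prep 20-25, US 35-55 (sonographer busy until 35)
  res <- run_session(pats, roster = micro_roster(), durations = dm)
  expect_equal(res$patients$finish_min, c(35, 55))
  expect_true(all(res$patients$completed))
  log <- res$log[order(res$log$end), ]
  expect_equal(log$activity, c(
    "initial_assessment", "initial_assessment", "ultrasound", "ultrasound"
  ))
  expect_equal(log$start, c(0, 10, 10, 20)) # imaging rows include prep
  expect_equal(log$end, c(10, 20, 35, 55))

  # a second sonographer removes the imaging wait: P2 finishes at 45
  res2 <- run_session(pats, roster = micro_roster(b7 = 2), durations = dm)
  expect_equal(res2$patients$finish_min, c(35, 45))
})

test_that("work in progress completes; queued patients overspill intact", {
  dm <- duration_model(dispersion = 0)
  pats <- tibble::tibble(activity_seq = list(c(1L), c(1L, 3L)))
  # close at 5 min: P1's assessment starts at 0 and runs past close to 10;
  # P2 never starts and leaves with the full remaining sequence
  res <- run_session(pats,
    roster = micro_roster(), durations = dm, close = 5
  )
  expect_equal(res$patients$completed, c(TRUE, FALSE))
  expect_equal(res$patients$finish_min[1], 10)
  expect_identical(res$patients$remaining_seq[[2]], c(1L, 3L))
  expect_equal(res$patients$activities_done[2], 0L)
})

test_that("prep and imaging are atomic: imaging may finish after close", {
  dm <- duration_model(dispersion = 0, prep = 5)
  pats <- tibble::tibble(activity_seq = list(3L))
  # prep starts at 0 within a 2-minute session? No: starts are allowed up
  # to the close instant, so with close = 2 the prep (and its imaging)
  # still run to completion once started at t = 0
  res <- run_session(pats,
    roster = micro_roster(), durations = dm, close = 2
  )
  expect_true(res$patients$completed)
  expect_equal(res$patients$finish_min, 25) # 5 prep + 20 ultrasound
})

test_that("biopsy seizes a consultant and an assistant together", {
  dm <- duration_model(dispersion = 0, biopsy = c(30, 30))
  pats <- tibble::tibble(activity_seq = list(4L, 4L))
  # one consultant + one assistant: biopsies serialise
  res <- run_session(pats, roster = micro_roster(), durations = dm)
  expect_equal(sort(res$patients$finish_min), c(30, 60))
  # two consultants but still one assistant: still serialised
  res2 <- run_session(pats,
    roster = micro_roster(consultant = 2), durations = dm
  )
  expect_equal(sort(res2$patients$finish_min), c(30, 60))
  # two of each: parallel
  res3 <- run_session(pats,
    roster = micro_roster(consultant = 2, g2 = 2), durations = dm
  )
  expect_equal(res3$patients$finish_min, c(30, 30))
})

test_that("thinned availability blocks a server after each task", {
  dm <- duration_model(dispersion = 0, prep = 5)
  pats <- tibble::tibble(activity_seq = list(3L, 3L))
  # assistant at availability 0.5: after the 5-min prep they are engaged on
  # other duties for another 5 min, so P2's prep starts at 10 not 5
  res <- run_session(pats,
    roster = micro_roster(
      b7 = 2, availability = c(
        consultant = 1, nurse_practitioner = 1, physician_associate = 1,
        band7_sonographer = 1, band6_sonographer = 1,
        band6_non_sonographer = 1, grade2_assistant = 0.5
      )
    ),
    durations = dm
  )
  expect_equal(res$patients$finish_min, c(25, 35)) # 10+5 prep, +20 imaging
})

test_that("staggered appointment times delay queue entry", {
  dm <- duration_model(dispersion = 0)
  pats <- tibble::tibble(
    activity_seq = list(1L, 1L), ready_min = c(0, 100)
  )
  res <- run_session(pats, roster = micro_roster(), durations = dm)
  expect_equal(res$patients$finish_min, c(10, 110))
})

test_that("session respects room limits", {
  dm <- duration_model(dispersion = 0)
  pats <- tibble::tibble(activity_seq = rep(list(1L), 6))
  # plenty of staff, one assessment room: strictly serial
  res <- run_session(pats,
    roster = micro_roster(consultant = 6),
    rooms = clinic_rooms(initial_assessment = 1),
    durations = dm
  )
  expect_equal(sort(res$patients$finish_min), seq(10, 60, by = 10))
})

test_that("empty bookings and already-finished patients are handled", {
  res <- run_session(
    tibble::tibble(activity_seq = list()),
    roster = micro_roster()
  )
  expect_equal(nrow(res$patients), 0)
  expect_equal(nrow(res$log), 0)
})
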