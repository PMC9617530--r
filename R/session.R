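#' Simulate a single clinic session
#'
#' Runs the discrete-event engine for one session: every booked patient is
#' present at the session start and works through their remaining activity
#' sequence, each step seizing a room of the right type plus eligible staff
#' (any free eligible member; patients are not pinned to one staff member).
#' Mammogram and ultrasound execute as an atomic preparation-then-imaging
#' subprocess in which the room is held from prep start to imaging end.
#' Queues are first-in-first-out. New activities may start up to the close
#' instant; work in progress always completes; patients still queued at close
#' are returned as overspill with their remaining sequence preserved.
#'
#' @param patients A data frame with an `activity_seq` list column of integer
#'   activity codes (see [sample_clinic_pathway()]); an optional
#'   `activities_done` column gives the number of leading activities already
#'   completed at a previous session (default 0), and an optional
#'   `ready_min` column gives each patient's appointment (arrival) time in
#'   minutes from session start (default 0: present at the start).
#' @param roster A [clinic_roster()].
#' @param rooms A [clinic_rooms()] vector.
#' @param durations A [duration_model()].
#' @param close Session length in minutes (new starts allowed up to this
#'   instant).
#' @return A list: `patients` (input tibble plus `completed`, `finish_min`
#'   — minutes from session start, `NA` for overspill — `activities_done`
#'   and `remaining_seq`), and `log`, a tibble of executed activities
#'   (`patient` row index, `activity`, `start`, `end`; prep time is included
#'   in the imaging interval).
#' @examples
#' pats <- tibble::tibble(activity_seq = list(c(1L, 3L), c(1L, 3L)))
#' res <- run_session(pats,
#'   roster = clinic_roster(
#'     consultant = 1, nurse_practitioner = 0, physician_associate = 0,
#'     band7_sonographer = 1, band6_sonographer = 0,
#'     band6_non_sonographer = 0, grade2_assistant = 1, availability = 1
#'   ),
#'   durations = duration_model(dispersion = 0)
#' )
#' res$patients$finish_min # 35, 55
#' @export
run_session <- function(patients, roster = clinic_roster(),
                        rooms = clinic_rooms(),
                        durations = duration_model(), close = 240) {
  stopifnot(
    is.data.frame(patients), "activity_seq" %in% names(patients),
    inherits(roster, "clinic_roster"),
    inherits(durations, "clinic_duration_model"), close >= 0
  )
  pos <- if ("activities_done" %in% names(patients)) {
    patients$activities_done
  } else {
    rep(0L, nrow(patients))
  }
  ready <- if ("ready_min" %in% names(patients)) {
    patients$ready_min
  } else {
    rep(0, nrow(patients))
  }
  res <- .run_session_engine(
    lapply(patients$activity_seq, as.integer), as.integer(pos),
    as.numeric(ready), as.integer(rooms), roster$counts,
    roster$availability, as.numeric(close), unclass(durations)
  )
  out <- as_tibble(patients)
  out$completed <- res$completed
  out$finish_min <- res$finish_time
  out$activities_done <- res$activities_done
  out$remaining_seq <- res$remaining
  log <- as_tibble(res$log)
  log$patient <- log$patient + 1L # engine indices are 0-based
  log$activity <- activity_names(log$activity)
  list(patients = out, log = log)
}
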