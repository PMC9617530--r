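#' Book patients into a clinic session
#'
#' Applies the booking discipline for one session: new patients are pulled
#' first-in-first-out from the referral queue, up to the queue-responsive
#' capacity ([plan_session_capacity()]); overspill returns are admitted
#' first-in-first-out from the clinic-returns queue, up to the session's
#' reserved return slots. Reserved return slots left unused are never
#' converted into new-patient slots.
#'
#' @param referral_queue_length Number of referred, not-yet-booked patients
#'   waiting at the session start instant.
#' @param returns_queue_length Number of overspill patients waiting to
#'   return.
#' @param kind,base_new_slots,overspill_slots Session properties (see
#'   [clinic_schedule()]).
#' @param rule A [booking_rule()].
#' @param bookable Number of queued patients referred early enough to be
#'   bookable into this session (booking notice); defaults to the whole
#'   queue.
#' @return A list: `n_new` (new patients booked), `n_returns` (returns
#'   admitted), `planned_capacity`.
#' @examples
#' book_session(100, 2, "full") # 25 new, 2 returns
#' @export
book_session <- function(referral_queue_length, returns_queue_length,
                         kind = "full", base_new_slots = NULL,
                         overspill_slots = if (kind == "full") 5L else 6L,
                         rule = booking_rule(),
                         bookable = referral_queue_length) {
  stopifnot(
    referral_queue_length >= 0, returns_queue_length >= 0,
    bookable <= referral_queue_length
  )
  n_returns <- min(
    as.integer(overspill_slots), as.integer(returns_queue_length)
  )
  planning_queue <- referral_queue_length +
    if (isTRUE(rule$include_returns)) n_returns else 0L
  cap <- plan_session_capacity(kind, planning_queue,
    base_new_slots = base_new_slots, rule = rule
  )
  list(
    n_new = min(cap, as.integer(bookable)),
    n_returns = n_returns,
    planned_capacity = cap
  )
}

#' Run one complete simulation trial
#'
#' Simulates the whole pathway over the warm-up plus collection horizon:
#' GP arrivals, cancer status and diagnostic pathway assignment, triage and
#' referral, the queue-responsive booking of weekly clinic sessions, and the
#' resource-constrained execution of each session including overspill
#' routing. Deterministic given `seed`.
#'
#' @param config A [clinic_config()].
#' @param seed Integer seed for this trial.
#' @return A `clinic_trial` object: a list with `patients` (one row per
#'   arrival: triage fields, `first_clinic_time`, `completion_time`,
#'   `overspill_events`, `booked`), `sessions` (one row per simulated
#'   session: queue lengths, planned capacity, bookings, admitted returns,
#'   overspill routings), plus `config` and `seed`.
#' @examples
#' \donttest{
#' trial <- run_trial(clinic_config(warmup_weeks = 2, collection_weeks = 4),
#'   seed = 1
#' )
#' compute_trial_metrics(trial)
#' }
#' @export
run_trial <- function(config = clinic_config(), seed = 1L) {
  validate_clinic_config(config)
  set.seed(as.integer(seed))
  horizon <- config$warmup_weeks + config$collection_weeks

  pats <- generate_patients(
    horizon_weeks = horizon, annual_volume = config$annual_volume,
    demand_multiplier = config$demand_multiplier,
    prevalence = config$prevalence, table = config$pathway,
    convention = config$arrival_convention
  )
  pats <- triage_patients(pats, config$triage)
  n_pat <- nrow(pats)

  # weekly schedule unrolled over the horizon
  wk <- clinic_schedule(config$disable_sessions)
  n_sess_wk <- nrow(wk)
  weeks <- seq_len(horizon) - 1L
  sess <- tibble(
    week = rep(weeks + 1L, each = n_sess_wk),
    session = rep(wk$session, times = horizon),
    kind = rep(wk$kind, times = horizon),
    start_abs = rep(weeks * MIN_PER_WEEK, each = n_sess_wk) +
      rep(wk$start_min, times = horizon),
    base_new_slots = rep(wk$base_new_slots, times = horizon),
    overspill_slots = rep(wk$overspill_slots, times = horizon)
  )
  n_sess <- nrow(sess)

  # referral queue: all referrals sorted by referral time (FIFO)
  referred <- which(!is.na(pats$referral_time))
  ord <- referred[order(pats$referral_time[referred], referred)]
  ref_time_sorted <- pats$referral_time[ord]
  n_ref <- length(ord)

  # per-patient outcome accumulators (plain vectors for speed)
  first_clinic <- rep(NA_real_, n_pat)
  completion <- rep(NA_real_, n_pat)
  overspill_events <- integer(n_pat)
  booked <- logical(n_pat)
  seqs <- pats$activity_seq

  # clinic-returns queue (FIFO ring on growing vectors)
  ret_cap <- 512L
  ret_ids <- integer(ret_cap)
  ret_entry <- numeric(ret_cap)
  ret_done <- integer(ret_cap) # activities already completed
  ret_head <- 1L
  ret_tail <- 0L

  s_queue <- integer(n_sess)
  s_retq <- integer(n_sess)
  s_cap <- integer(n_sess)
  s_new <- integer(n_sess)
  s_ret <- integer(n_sess)
  s_over <- integer(n_sess)

  # two referral-queue pointers: `inq` counts everyone referred by the
  # session start (drives the capacity rule); `elig` counts those referred
  # early enough to have received an appointment (booking notice)
  notice_min <- (config$booking_notice_days %||% 0) * MIN_PER_DAY
  spread_min <- config$appointment_spread_min %||% 0
  inq <- 0L
  elig <- 0L
  taken <- 0L # referrals already booked
  rooms <- as.integer(config$rooms)
  dur_pars <- unclass(config$durations)
  rosters <- list(
    full = config$roster_full, add_on = config$roster_addon
  )
  sess_kind <- sess$kind
  sess_start <- sess$start_abs
  sess_base <- sess$base_new_slots
  sess_over <- sess$overspill_slots

  for (s in seq_len(n_sess)) {
    t0 <- sess_start[s]
    while (inq < n_ref && ref_time_sorted[inq + 1L] <= t0) {
      inq <- inq + 1L
    }
    # the notice phases in over the first two notice-lengths so the empty
    # system does not start with an artificially frozen appointment diary
    eff_notice <- if (notice_min > 0) {
      notice_min * min(1, t0 / (2 * notice_min))
    } else {
      0
    }
    while (elig < n_ref && ref_time_sorted[elig + 1L] <= t0 - eff_notice) {
      elig <- elig + 1L
    }
    q_len <- inq - taken
    n_wait_ret <- 0L
    while (ret_head + n_wait_ret <= ret_tail &&
      ret_entry[ret_head + n_wait_ret] <= t0) {
      n_wait_ret <- n_wait_ret + 1L
    }
    bk <- book_session(q_len, n_wait_ret,
      kind = sess_kind[s], base_new_slots = sess_base[s],
      overspill_slots = sess_over[s], rule = config$rule,
      bookable = elig - taken
    )
    n_new <- bk$n_new
    n_retn <- bk$n_returns
    s_queue[s] <- q_len
    s_retq[s] <- n_wait_ret
    s_cap[s] <- bk$planned_capacity
    s_new[s] <- n_new
    s_ret[s] <- n_retn
    if (n_new + n_retn == 0L) next

    ids_ret <- if (n_retn > 0L) ret_ids[ret_head:(ret_head + n_retn - 1L)]
      else integer(0)
    pos_ret <- if (n_retn > 0L) ret_done[ret_head:(ret_head + n_retn - 1L)]
      else integer(0)
    ret_head <- ret_head + n_retn
    ids_new <- if (n_new > 0L) ord[(taken + 1L):(taken + n_new)]
      else integer(0)
    taken <- taken + n_new

    ids <- c(ids_ret, ids_new) # returns first: they queued earlier
    pos <- c(pos_ret, integer(n_new))
    booked[ids_new] <- TRUE
    first_clinic[ids_new] <- t0

    # appointment times spaced evenly across the booking window
    n_bk <- length(ids)
    ready <- if (spread_min > 0 && n_bk > 1L) {
      (seq_len(n_bk) - 1L) / n_bk * spread_min
    } else {
      numeric(n_bk)
    }
    res <- .run_session_engine(
      seqs[ids], pos, ready, rooms,
      rosters[[sess_kind[s]]]$counts, rosters[[sess_kind[s]]]$availability,
      240, dur_pars
    )
    comp <- res$completed
    completion[ids[comp]] <- t0 + res$finish_time[comp]
    n_over <- sum(!comp)
    s_over[s] <- n_over
    if (n_over > 0L) {
      over_idx <- which(!comp)
      if (ret_tail + n_over > ret_cap) {
        grow <- max(ret_cap, n_over)
        ret_ids <- c(ret_ids, integer(grow))
        ret_entry <- c(ret_entry, numeric(grow))
        ret_done <- c(ret_done, integer(grow))
        ret_cap <- ret_cap + grow
      }
      sl <- (ret_tail + 1L):(ret_tail + n_over)
      ret_ids[sl] <- ids[over_idx]
      ret_entry[sl] <- t0 + 240
      ret_done[sl] <- res$activities_done[over_idx]
      ret_tail <- ret_tail + n_over
      overspill_events[ids[over_idx]] <- overspill_events[ids[over_idx]] + 1L
    }
  }

  # never-referred patients exit the model at their GP presentation
  never <- pats$referral_kind == "none"
  completion[never] <- pats$gp_arrival_time[never]

  pats$first_clinic_time <- first_clinic
  pats$completion_time <- completion
  pats$overspill_events <- overspill_events
  pats$booked <- booked

  sess$queue_length <- s_queue
  sess$returns_backlog <- s_retq
  sess$planned_capacity <- s_cap
  sess$n_new_booked <- s_new
  sess$n_returns_admitted <- s_ret
  sess$n_overspill <- s_over

  structure(
    list(
      patients = pats, sessions = sess, config = config, seed = seed
    ),
    class = "clinic_trial"
  )
}

#' @export
print.clinic_trial <- function(x, ...) {
  cat(
    "<clinic_trial> seed", x$seed, "-", nrow(x$patients), "arrivals,",
    nrow(x$sessions), "sessions over",
    x$config$warmup_weeks + x$config$collection_weeks, "weeks\n"
  )
  invisible(x)
}
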