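#' Deterministic per-trial seeds
#'
#' A stable 32-bit polynomial hash of the master seed, strategy name and
#' trial index, kept in `[1, 2^31 - 2]`. Setting `paired = TRUE` drops the
#' strategy name so that trial `i` shares its random numbers across
#' strategies (common random numbers).
#'
#' @param master Master integer seed.
#' @param strategy Strategy name.
#' @param trial Trial index (1-based).
#' @param paired Use common random numbers across strategies?
#' @return Integer seed.
#' @export
trial_seed <- function(master, strategy, trial, paired = FALSE) {
  key <- if (paired) {
    paste0(master, "|", trial)
  } else {
    paste0(master, "|", strategy, "|", trial)
  }
  h <- 5381
  for (c in utf8ToInt(key)) {
    h <- (h * 33 + c) %% 2147483629
  }
  as.integer(h + 1)
}

#' Named strategy presets
#'
#' The experiment arms reported for the clinic: standard care, the two
#' test-adoption scenarios, and the three service reconfigurations (applied
#' with Scenario 2 parameters).
#'
#' @return A named list of [clinic_config()] argument lists.
#' @export
strategy_presets <- function() {
  list(
    standard_care = list(triage = scenario_standard_care()),
    scenario1 = list(triage = scenario_pinpoint_1()),
    scenario2 = list(triage = scenario_pinpoint_2()),
    scenario2_no_tue_am = list(
      triage = scenario_pinpoint_2(), disable_sessions = "tue_am"
    ),
    scenario2_no_wed_am = list(
      triage = scenario_pinpoint_2(), disable_sessions = "wed_am"
    ),
    scenario2_no_tue_wed_am = list(
      triage = scenario_pinpoint_2(), disable_sessions = c("tue_am", "wed_am")
    )
  )
}

#' Run a replicated simulation experiment
#'
#' Runs `n_trials` independent trials of each named strategy, with per-trial
#' seeds derived deterministically from the master seed, and summarises every
#' outcome metric with mean and 95% CI across trials. Each trial uses a
#' fresh engine; no state leaks across strategies or trials.
#'
#' @param strategies A named list. Each element is either a `clinic_config`
#'   or a list of arguments to [clinic_config()] (see [strategy_presets()]).
#' @param n_trials Trials per strategy.
#' @param seed Master seed.
#' @param paired Use common random numbers across strategies?
#' @param base_config A `clinic_config` whose fields are used as defaults for
#'   strategies given as argument lists (so a calibrated roster or altered
#'   demand applies to every arm).
#' @param progress Print one line per completed strategy?
#' @return A `clinic_experiment` object: list with `trials` (tidy per-trial
#'   metrics, one row per strategy x trial), `summary` (a
#'   [summarize_trials()] table), `n_trials`, `seed`.
#' @examples
#' \donttest{
#' exp <- run_experiment(strategy_presets()[c("standard_care", "scenario1")],
#'   n_trials = 2, seed = 1
#' )
#' tidy(exp)
#' }
#' @export
run_experiment <- function(strategies, n_trials = 150, seed = 1,
                           paired = FALSE, base_config = NULL,
                           progress = FALSE) {
  stopifnot(is.list(strategies), length(strategies) > 0)
  if (is.null(names(strategies)) || anyDuplicated(names(strategies)) ||
    any(names(strategies) == "")) {
    abort("`strategies` must have unique non-empty names.")
  }
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  configs <- lapply(strategies, function(s) {
    if (inherits(s, "clinic_config")) {
      return(s)
    }
    if (!is.list(s)) abort("Each strategy must be a config or argument list.")
    args <- s
    if (!is.null(base_config)) {
      defaults <- base_config[setdiff(names(base_config), names(args))]
      args <- c(args, defaults)
    }
    do.call(clinic_config, args)
  })
  # validate everything before simulating anything
  lapply(configs, validate_clinic_config)

  trials <- purrr::imap(configs, function(cfg, name) {
    rows <- purrr::map(seq_len(n_trials), function(i) {
      s <- trial_seed(seed, name, i, paired = paired)
      m <- compute_trial_metrics(run_trial(cfg, seed = s))
      dplyr::bind_cols(tibble(strategy = name, trial = i, seed = s), m)
    })
    out <- dplyr::bind_rows(rows)
    if (progress) {
      message(sprintf(
        "strategy %s: %d trials, mean TWW %.1f%%", name, n_trials,
        mean(out$tww_pct_overall)
      ))
    }
    out
  })
  trials <- dplyr::bind_rows(trials) %>%
    mutate(strategy = factor(.data$strategy, levels = names(configs)))
  summary <- if (n_trials >= 2) {
    summarize_trials(trials)
  } else {
    NULL # CI undefined with a single trial
  }
  structure(
    list(
      trials = trials, summary = summary, n_trials = n_trials, seed = seed,
      strategies = names(configs)
    ),
    class = "clinic_experiment"
  )
}

#' @export
print.clinic_experiment <- function(x, ...) {
  cat(
    "<clinic_experiment>", length(x$strategies), "strategies x",
    x$n_trials, "trials (master seed", paste0(x$seed, ")\n")
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Sensitivity sweep over configuration parameters
#'
#' Re-runs an experiment over a grid of parameter values. Axes address
#' top-level [clinic_config()] arguments (e.g. `demand_multiplier`,
#' `prevalence`) or [triage_config()] fields prefixed `triage.` (e.g.
#' `triage.gp_override`, `triage.delayed_return_noncancer`,
#' `triage.sensitivity`). Values on each axis are deduplicated.
#'
#' @param base A `clinic_config` used as the baseline arm.
#' @param grid Named list of parameter value vectors; the sweep is the
#'   Cartesian product.
#' @param n_trials,seed,paired As in [run_experiment()].
#' @return A tibble of per-trial metrics in long format, one row per
#'   grid point x trial, with one column per swept parameter.
#' @examples
#' \donttest{
#' cfg <- clinic_config(warmup_weeks = 2, collection_weeks = 4)
#' sensitivity_sweep(cfg, list(demand_multiplier = c(1, 1.1)), n_trials = 2)
#' }
#' @export
sensitivity_sweep <- function(base = clinic_config(), grid, n_trials = 150,
                              seed = 1, paired = FALSE) {
  stopifnot(inherits(base, "clinic_config"), is.list(grid), length(grid) > 0)
  if (is.null(names(grid)) || any(names(grid) == "")) {
    abort("`grid` axes must be named.")
  }
  cfg_fields <- setdiff(names(base), "triage")
  triage_fields <- setdiff(names(base$triage), "arm")
  for (nm in names(grid)) {
    tri <- startsWith(nm, "triage.")
    fld <- sub("^triage\\.", "", nm)
    if ((tri && !(fld %in% triage_fields)) ||
      (!tri && !(nm %in% cfg_fields))) {
      abort(paste0("Unknown sweep parameter: ", nm))
    }
    grid[[nm]] <- unique(grid[[nm]])
  }
  points <- tidyr::expand_grid(!!!grid)
  res <- purrr::map(seq_len(nrow(points)), function(i) {
    cfg <- base
    for (nm in names(grid)) {
      v <- points[[nm]][i]
      if (startsWith(nm, "triage.")) {
        cfg$triage[[sub("^triage\\.", "", nm)]] <- v
      } else {
        cfg[[nm]] <- v
      }
    }
    cfg <- validate_clinic_config(cfg)
    name <- paste(
      purrr::imap_chr(points[i, ], ~ paste0(.y, "=", .x)),
      collapse = ","
    )
    ex <- run_experiment(setNames(list(cfg), name),
      n_trials = n_trials,
      seed = seed, paired = paired
    )
    dplyr::bind_cols(points[rep(i, nrow(ex$trials)), ], ex$trials)
  })
  dplyr::bind_rows(res)
}

#' Calibrate the staff roster to an audited overspill count
#'
#' The roster's availability fraction and the imaging preparation time are
#' the two load-bearing unknowns of intra-clinic throughput. This routine
#' coordinate-searches them so that the standard-care arm's mean annual
#' overspill appointment count matches an audited target. Each evaluation
#' runs a reduced number of trials; the returned object reports the achieved
#' value, the search trace, and whether the tolerance was met (a failure is
#' reported, not silently accepted).
#'
#' @param target Audited annual overspill appointments.
#' @param base A `clinic_config` to calibrate (its triage arm is forced to
#'   standard care for evaluation).
#' @param availability_bounds,prep_bounds Search bounds.
#' @param n_trials Trials per evaluation.
#' @param seed Master seed (evaluations are deterministic).
#' @param n_grid Grid points per coordinate pass.
#' @param passes Coordinate passes.
#' @param tol Relative tolerance on the achieved mean.
#' @return A `clinic_calibration` list: `availability`, `prep`, `achieved`,
#'   `target`, `converged`, `trace` (tibble of evaluations), and `config`
#'   (the calibrated configuration).
#' @export
calibrate_roster <- function(target = 1664, base = clinic_config(),
                             availability_bounds = c(0.5, 1),
                             prep_bounds = c(2, 10),
                             n_trials = 20, seed = 1, n_grid = 5,
                             passes = 2, tol = 0.05) {
  stopifnot(
    inherits(base, "clinic_config"), target > 0,
    availability_bounds[1] > 0, availability_bounds[2] <= 1,
    diff(availability_bounds) > 0, diff(prep_bounds) > 0, n_grid >= 3
  )
  trace <- list()
  evaluate <- function(avail, prep) {
    cfg <- base
    cfg$triage <- scenario_standard_care()
    cfg$roster_full <- clinic_roster(
      consultant = base$roster_full$counts[["consultant"]],
      nurse_practitioner = base$roster_full$counts[["nurse_practitioner"]],
      physician_associate = base$roster_full$counts[["physician_associate"]],
      band7_sonographer = base$roster_full$counts[["band7_sonographer"]],
      band6_sonographer = base$roster_full$counts[["band6_sonographer"]],
      band6_non_sonographer =
        base$roster_full$counts[["band6_non_sonographer"]],
      grade2_assistant = base$roster_full$counts[["grade2_assistant"]],
      availability = avail
    )
    cfg$roster_addon <- addon_roster(cfg$roster_full)
    cfg$durations$prep <- prep
    vals <- vapply(seq_len(n_trials), function(i) {
      tr <- run_trial(cfg, seed = trial_seed(seed, "calibration", i))
      compute_trial_metrics(tr)$overspill_appointments
    }, numeric(1))
    m <- mean(vals)
    trace[[length(trace) + 1L]] <<- tibble(
      availability = avail, prep = prep, mean_overspill = m
    )
    m
  }
  memo <- new.env(parent = emptyenv())
  eval_memo <- function(avail, prep) {
    key <- paste(signif(avail, 10), signif(prep, 10))
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    v <- evaluate(avail, prep)
    memo[[key]] <- v
    v
  }
  cur <- c(
    avail = mean(availability_bounds),
    prep = base$durations$prep
  )
  cur[["prep"]] <- min(max(cur[["prep"]], prep_bounds[1]), prep_bounds[2])
  for (pass in seq_len(passes)) {
    for (coord in c("avail", "prep")) {
      bounds <- if (coord == "avail") availability_bounds else prep_bounds
      f <- function(v) {
        if (coord == "avail") {
          eval_memo(v, cur[["prep"]])
        } else {
          eval_memo(cur[["avail"]], v)
        }
      }
      cand <- seq(bounds[1], bounds[2], length.out = n_grid)
      resid <- vapply(cand, function(v) f(v) - target, numeric(1))
      # locate a sign change (the response is monotone in each coordinate)
      # and bisect inside it; otherwise keep the closest grid point
      ix <- which(resid[-1] * resid[-length(resid)] <= 0)
      if (length(ix)) {
        i <- ix[which.min(pmin(
          abs(resid[ix]), abs(resid[ix + 1L])
        ))]
        lo <- cand[i]
        hi <- cand[i + 1L]
        rlo <- resid[i]
        best_v <- if (abs(rlo) < abs(resid[i + 1L])) lo else hi
        best_r <- min(abs(rlo), abs(resid[i + 1L]))
        for (b in 1:4) {
          mid <- (lo + hi) / 2
          rm <- f(mid) - target
          if (abs(rm) < best_r) {
            best_r <- abs(rm)
            best_v <- mid
          }
          if (rm * rlo <= 0) {
            hi <- mid
          } else {
            lo <- mid
            rlo <- rm
          }
        }
        cur[[coord]] <- best_v
      } else {
        cur[[coord]] <- cand[which.min(abs(resid))]
      }
    }
  }
  final <- eval_memo(cur[["avail"]], cur[["prep"]])
  cfg <- base
  cfg$roster_full$availability[] <- cur[["avail"]]
  cfg$roster_addon$availability[] <- cur[["avail"]]
  cfg$durations$prep <- cur[["prep"]]
  structure(
    list(
      availability = unname(cur[["avail"]]), prep = unname(cur[["prep"]]),
      achieved = final, target = target,
      converged = abs(final - target) / target <= tol,
      trace = dplyr::bind_rows(trace), config = cfg
    ),
    class = "clinic_calibration"
  )
}

#' @export
print.clinic_calibration <- function(x, ...) {
  cat(
    "<clinic_calibration> availability", round(x$availability, 3),
    "prep", round(x$prep, 2), "min ->", round(x$achieved, 1),
    "overspills (target", x$target,
    if (x$converged) "- converged)\n" else "- NOT within tolerance)\n"
  )
  invisible(x)
}
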