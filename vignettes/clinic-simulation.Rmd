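---
title: "Modelling a two-week-wait breast clinic with clinicflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a two-week-wait breast clinic with clinicflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinicflow)
```

## The system being modelled

`clinicflow` is a discrete-event simulation of a single large UK symptomatic
breast clinic operating the two-week-wait (TWW) referral pathway: patients
presenting to their GP with breast symptoms are referred to a specialist
clinic, with a national target that they be seen within fourteen days of
referral. The model tracks individual patients from GP presentation through
referral, a queue for clinic appointments, and a sequence of
resource-constrained diagnostic activities (initial assessment, mammogram,
ultrasound, biopsy), to exit with or without a cancer diagnosis.

The question the model is built to answer: if primary care could *rule out*
low-risk patients with a blood-based risk test — characterised purely by its
sensitivity and specificity — how much clinic pressure would be relieved, as
measured by (i) the percentage of patients seen within the TWW target and
(ii) the number of "overspill" appointments, i.e. return visits needed
because a patient's diagnostics could not all be completed in their original
session?

## Model structure

One simulated **trial** covers a 12-week warm-up (discarded; it populates
the queues so the results year starts from realistic congestion) plus a
52-week results-collection period. Weeks are the scheduling unit throughout;
a year is exactly 52 weeks.

1. **Arrivals.** Symptomatic presentations form a homogeneous Poisson
   process with an expected 10,542 arrivals per 52-week year (configurable;
   a literal exponential-interarrival convention with a restricted weekly
   arrival window is available as `generate_arrivals(convention =
   "interarrival")`, and gives the same weekly volume). Cancer status is an
   independent Bernoulli draw at 4.76% prevalence.

2. **Triage.** Under standard care every patient is referred immediately.
   Under the test arm, each patient is classified high risk (probability =
   sensitivity, for cancer) or low risk (probability = specificity, for
   non-cancer). High-risk results are referred when the result returns;
   low-risk results may be overruled by the GP (independent Bernoulli);
   remaining non-referred patients may return with persisting symptoms
   after a fixed six weeks and receive a delayed referral (probability 1
   for cancer in both shipped scenarios; 0 or 0.10 for non-cancer). The
   scenario presets are `scenario_pinpoint_1()` (full adherence, no
   non-cancer returns) and `scenario_pinpoint_2()` (20% GP override, 10%
   non-cancer delayed returns). `referral_fraction_closed_form()` gives the
   analytic referral fractions these rules imply and serves as the oracle
   for the simulated ones.

3. **Booking.** The clinic runs seven weekly four-hour "full" sessions plus
   one reduced "add-on" session (Tue AM). Sessions book new patients
   first-in-first-out from the referral queue: 25 per full session by
   default, expanding by one patient per 15 queued above a threshold of 380
   up to 34, and 10 (fixed) for the add-on session. Each full session also
   reserves 5 slots (add-on: 6) for overspill returns; unused reserves are
   never converted to new-patient slots. Booked patients receive staggered
   appointment times across the session (see *Reconstructed operational
   details*).

4. **The clinic floor.** Each activity seizes one room of its type (4
   assessment, 3 mammography, 4 ultrasound, 4 biopsy) plus eligible staff:
   assessment needs one of consultant/nurse practitioner/physician
   associate; mammography any qualified radiographer; ultrasound a Band 6
   or 7 sonographer; biopsy a consultant *and* a Grade 2 or Band 6
   assistant. Mammogram and ultrasound begin with a 5-minute patient
   preparation step (Grade 2 or Band 6) run as an atomic subprocess: the
   room is seized at prep start and held through imaging, and a patient is
   only picked up for prep once an imaging room is free. Biopsy preparation
   is folded into the biopsy duration. Patients are not pinned to a staff
   member: any free eligible member serves the head of the queue. New
   activities may start up to the close instant; started work always
   completes (the clinic's overtime allowance); patients still queued at
   close are routed to the returns queue with their remaining sequence
   preserved, each routing counted as one overspill appointment.

5. **Outcomes.** A patient "completes the model" when they exit during the
   collection window — after finishing all activities, after discharge at
   initial assessment (25% of non-cancer patients), or at presentation if
   never referred. Time to clinic is counted in elapsed Mon-Fri weekdays
   from GP presentation to first attendance; the TWW target is met when
   first attendance falls within fourteen calendar days of presentation, so
   a six-week delayed return always misses it. Trials are summarised with
   means and two-sided 95% t-intervals (150 trials by default).

## Activity mix and durations

The diagnostic pathway mix is the audit-derived `pathway_table()`: nine
sequences with separate probabilities for the cancer and non-cancer strata
(non-cancer patients mostly ultrasound-only or mammogram+ultrasound; cancer
patients mostly the full triple assessment). Labels containing both imaging
modalities are ordered mammogram-first with probability 0.60 at sampling
time. Every cancer patient requires a biopsy: if the drawn sequence lacks
one, it is appended — a clinical-practice assumption, since a sequence
without histology cannot yield a cancer diagnosis.

Durations are symmetric triangular around stated central values (assessment
10 min, mammogram 20, ultrasound 20) with a ±25% half-width — bounded,
positive, and median-preserving, which is what "some variation around the
expected timings" needs; biopsy is an equal two-point mixture of 30 and 45
minutes. Setting `dispersion = 0` makes every duration exact, which is how
the hand-simulated micro-instance oracles in the test suite pin down the
engine's event ordering exactly.

## Staff availability as thinned capacity

Rostered staff spend part of each shift on administrative and follow-up
work. This is modelled as *thinned capacity*: after serving a task of
length `d`, a server is blocked for `d (1 - a) / a` minutes, so a role with
`n` staff at availability `a` supplies `n × a` effective servers in the
long run, smoothly in `a`. The alternative — explicit scheduled breaks —
would need shift-level detail the model does not otherwise require.
Availability is per-role configurable; the shipped value is calibrated (see
below).

## Reconstructed operational details

Four operational details of the real clinic are not fixed by its published
headline parameters; the package reconstructs them and anchors each to an
audited quantity. They are ordinary configuration, so all are overridable.

- **Capacity planning counts the session's admitted returns.** The
  queue-responsive rule reads the "clinic queue" as the session's total
  pending load: waiting new referrals plus the overspill returns the
  session will see (`booking_rule(include_returns = TRUE)`). The
  referral-only reading is available but reproduces the clinic's audited
  TWW performance less well. The rule's step rounding (floor / nearest /
  ceiling — all consistent with "one more patient per additional 15 in the
  queue") defaults to floor.

- **Test turnaround of one week.** The risk test is drawn at the GP visit,
  but the referral decision follows the laboratory result. The default
  `test_turnaround_min` of 7 days reproduces the audited
  referral-to-clinic interval of an *uncongested* clinic (about 5.5-6
  weekdays), which a same-day decision cannot: with the queue drained,
  patients would otherwise be seen within a day or two. The same lag is
  what makes removing a full weekly session collapse TWW performance —
  half the fourteen-day budget is already spent before the clinic queue is
  joined. Standard care involves no test and is unaffected.

- **Staggered appointment times.** Booked patients are given evenly spaced
  appointment times across the first 190 minutes of the 240-minute session
  (`appointment_spread_min`), overspill returns first, as clinics do in
  practice. With everyone present at the session start, an uncongested
  session almost never overspills and the model understates scenario-arm
  overspill by roughly 20%; staggering restores the audited relationship
  between session load and overspill across all strategy arms.

- **Calibrated availability.** With the roster shape fixed (full session:
  2 consultants, 1 NP, 1 PA, 2 Band 7, 1+1 Band 6, 2 Grade 2; add-on
  session: half, rounded up), the availability fraction is the one
  load-bearing free parameter. `calibrate_roster()` coordinate-searches
  availability and prep duration — grid scan, then bisection inside the
  bracketing interval, using 20 reduced trials per evaluation — against the
  audited annual standard-care overspill count. The shipped default is
  0.672 with prep at 5 minutes; the routine reports its achieved value and
  flags failure to converge rather than accepting it silently.

## Numerical and design choices

- **Queues** are strictly FIFO everywhere, with head-of-line blocking
  within each activity queue. When several staff are eligible, the least
  specialised is seized first (Grade 2 before Band 6 before Band 7 for
  prep; Band 6 before Band 7 for mammography; NP/PA before consultant for
  assessment) to conserve scarce sonographers and consultants.
- **Tie-breaks at equal event times** are resolved in event-creation order,
  which makes every trial bit-reproducible for a given seed. All
  randomness flows from the single R RNG stream seeded once per trial;
  per-trial seeds come from a stable 32-bit hash of master seed, strategy
  name and trial index (`trial_seed()`), with a paired mode for common
  random numbers.
- **Delayed returns** join the same FIFO referral queue as new referrals at
  exactly presentation + turnaround + six weeks; no distribution is placed
  on the delay.
- **Degenerate inputs** are legal where they are meaningful: zero demand
  gives an empty stream, a fully disabled schedule leaves every referral
  queued, zero dispersion gives exact durations. Configurations in which
  some activity has no eligible staff anywhere in the roster are rejected
  before simulation (`validate_clinic_config()`).
- **MDT and diagnosis exits** are instantaneous and unresourced.

## What the generator does and does not emulate

The synthetic population reproduces: the annual referral volume and its
Poisson week-to-week variation, the cancer prevalence among TWW referrals,
the audited mix of diagnostic sequences, and activity-duration spread. It
deliberately omits: symptom type, age and tumour-stage structure; seasonal
and day-of-week demand patterns; did-not-attend behaviour; follow-up and
treatment appointments; and any internal structure of the risk test beyond
sensitivity and specificity. Tests passing on this population therefore
validate the queueing and booking mechanics under the stated aggregate
conditions — not patient-level realism, and not the test's clinical
performance, which enters only as two fixed operating-point numbers.

## Problem sizes

One default trial simulates 64 weeks (≈ 13,000 patients, ≈ 510 sessions)
and runs in about a quarter of a second; the full replicated experiment —
150 trials per strategy arm, the package's default — takes half a minute
per arm on one core. The test suite uses small horizons (2 + 6 weeks) for
structural properties and full-length 150-trial experiments for the
published-outcome checks; the calibration routine uses 20 trials per
evaluation with a full-length confirmation.

## Known limitations

- The reconstruction of unpublished operational detail (turnaround,
  appointment spread, availability) is anchored to a handful of audited
  aggregates; other combinations could fit them too, and conclusions
  should not lean on any single reconstructed value.
- Under a 10% demand increase the standard-care TWW percentage simulates
  about one booking-rule notch below the audited clinic's behaviour — the
  discrete capacity rule makes steady-state waits sensitive at the
  half-step level.
- The model is single-site; rosters, room counts and the booking rule are
  those of one large clinic and transfer to other clinics only by
  reconfiguration.
- No costs, health outcomes, or prioritisation (fast-tracking) use of the
  risk test are modelled.

## A worked run

```{r example, eval = FALSE}
library(clinicflow)

exp <- run_experiment(
  strategy_presets()[c("standard_care", "scenario1", "scenario2")],
  n_trials = 150, seed = 1
)
tidy(exp)
autoplot(exp)
```

`tidy()` returns the headline table (completions, mean weekdays to clinic,
TWW percentage and overspill count per strategy, each with a 95% CI across
trials); `write_experiment_csv()` exports the per-trial metrics and the
summary; `sensitivity_sweep()` re-runs a strategy over parameter grids such
as `triage.gp_override` up to 0.5 or `demand_multiplier = 1.10`.
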