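# Shared fixtures for the test suite. Everything is generated in code.

# a small-horizon configuration for fast structural tests
quick_config <- function(triage = scenario_standard_care(), ...) {
  clinic_config(
    triage = triage, warmup_weeks = 2, collection_weeks = 6, ...
  )
}

# single-role rosters for hand-simulated micro instances
micro_roster <- function(consultant = 1, np = 0, pa = 0, b7 = 1, b6s = 0,
                         b6ns = 0, g2 = 1, availability = 1) {
  clinic_roster(
    consultant = consultant, nurse_practitioner = np,
    physician_associate = pa, band7_sonographer = b7,
    band6_sonographer = b6s, band6_non_sonographer = b6ns,
    grade2_assistant = g2, availability = availability
  )
}

# binomial sampling band: |phat - p| <= k * sqrt(p (1 - p) / n)
expect_within_binomial_band <- function(phat, p, n, k = 4) {
  expect_lt(abs(phat - p), k * sqrt(p * (1 - p) / n) + 1e-12)
}
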