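test_that("arrival stream has the configured annual volume and structure", {
  set.seed(101)
  counts <- replicate(30, length(generate_arrivals(52)))
  # Poisson(10542): mean of 30 replicates within 3 standard errors
  expect_lt(abs(mean(counts) - 10542), 3 * sqrt(10542 / 30))

  arr <- generate_arrivals(4)
  expect_true(all(diff(arr) > 0))
  expect_true(all(arr >= 0 & arr <= 4 * 7 * 1440))

  expect_identical(generate_arrivals(52, demand_multiplier = 0), numeric(0))
  expect_error(generate_arrivals(0), "horizon_weeks")
  expect_error(generate_arrivals(52, annual_volume = -1), "annual_volume")

  # demand multiplier scales the expected volume
  set.seed(102)
  n110 <- mean(replicate(20, length(generate_arrivals(52,
    demand_multiplier = 1.10
  ))))
  expect_lt(abs(n110 - 10542 * 1.1), 4 * sqrt(10542 * 1.1 / 20))
})

test_that("interarrival-window convention preserves the weekly volume", {
  set.seed(103)
  counts <- replicate(20, length(
    generate_arrivals(52, convention = "interarrival")
  ))
  expect_lt(abs(mean(counts) - 10542), 4 * sqrt(10542 / 20))
  arr <- generate_arrivals(4, convention = "interarrival")
  expect_true(all(diff(arr) > 0))
  # arrivals fold into the weekly window (about 55 h from Monday 00:00)
  window <- 16.2778 * 10542 / 52
  expect_true(all(arr %% (7 * 1440) <= window))
})

test_that("weekly arrival counts behave as a homogeneous Poisson process", {
  set.seed(104)
  arr <- generate_arrivals(80)
  wk <- tabulate(floor(arr / (7 * 1440)) + 1L, nbins = 80)
  # index of dispersion test: var/mean ~ chi-square(n-1)/(n-1) under Poisson
  stat <- (80 - 1) * var(wk) / mean(wk)
  expect_gt(stat, qchisq(0.005, df = 79))
  expect_lt(stat, qchisq(0.995, df = 79))
})

test_that("cancer status is Bernoulli at the configured prevalence", {
  set.seed(105)
  pats <- assign_cancer(tibble::tibble(id = 1:1e5), prevalence = 0.0476)
  expect_within_binomial_band(mean(pats$has_cancer), 0.0476, 1e5, k = 2.58)

  expect_false(any(assign_cancer(tibble::tibble(id = 1:50),
    prevalence = 0
  )$has_cancer))
  expect_true(all(assign_cancer(tibble::tibble(id = 1:50),
    prevalence = 1
  )$has_cancer))
  expect_error(assign_cancer(tibble::tibble(id = 1), prevalence = 1.2))
})

test_that("clinic pathways recover the audit sequence mix", {
  set.seed(106)
  tab <- pathway_table()
  n <- 1e5
  pats <- sample_clinic_pathway(
    tibble::tibble(id = seq_len(n), has_cancer = FALSE),
    table = tab
  )
  imaged <- pats[!pats$discharged_after_assessment, ]
  # discharge fraction
  expect_within_binomial_band(
    mean(pats$discharged_after_assessment), 0.25, n
  )
  # per-label frequencies within 4 binomial standard errors
  freq <- table(factor(imaged$pathway_label, levels = tab$label)) /
    nrow(imaged)
  for (i in seq_len(9)) {
    expect_within_binomial_band(
      unname(freq[i]), tab$p_noncancer[i], nrow(imaged)
    )
  }
  # modality order: 60% mammogram-first among dual-modality draws
  dual <- imaged$pathway_label %in% c(
    "mammogram_ultrasound", "ultrasound_mammogram",
    "mammogram_ultrasound_biopsy", "ultrasound_mammogram_biopsy"
  )
  first_img <- vapply(
    imaged$activity_seq[dual], function(s) s[2], integer(1)
  )
  expect_within_binomial_band(mean(first_img == 2L), 0.60, sum(dual))
})

test_that("every sequence starts with assessment; cancer implies one biopsy", {
  set.seed(107)
  pats <- sample_clinic_pathway(
    assign_cancer(tibble::tibble(id = 1:20000), prevalence = 0.3)
  )
  expect_true(all(vapply(pats$activity_seq, function(s) s[1] == 1L,
    logical(1)
  )))
  n_biopsy <- vapply(pats$activity_seq, function(s) sum(s == 4L), integer(1))
  expect_true(all(n_biopsy[pats$has_cancer] == 1L))
  expect_true(all(n_biopsy <= 1L))
  # discharged patients: non-cancer, assessment only
  disch <- pats$discharged_after_assessment
  expect_false(any(pats$has_cancer[disch]))
  expect_true(all(lengths(pats$activity_seq[disch]) == 1L))
})

test_that("a cancer mammogram-only draw gains a terminal biopsy", {
  tab <- pathway_table(
    probs_noncancer = c(1, 0, 0, 0, 0, 0, 0, 0, 0),
    probs_cancer = c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  set.seed(108)
  pats <- sample_clinic_pathway(
    tibble::tibble(id = 1:5, has_cancer = TRUE),
    table = tab
  )
  for (s in pats$activity_seq) expect_identical(s, c(1L, 2L, 4L))
  # biopsy-only draw is not doubled
  tab2 <- pathway_table(
    probs_noncancer = c(0, 0, 0, 0, 0, 0, 0, 1, 0),
    probs_cancer = c(0, 0, 0, 0, 0, 0, 0, 1, 0)
  )
  pats2 <- sample_clinic_pathway(
    tibble::tibble(id = 1:5, has_cancer = TRUE),
    table = tab2
  )
  for (s in pats2$activity_seq) expect_identical(s, c(1L, 4L))
})

test_that("pathway table validates its probabilities", {
  expect_error(pathway_table(probs_noncancer = rep(0.2, 9)), "sum to 1")
  expect_error(pathway_table(mammogram_first = 1.5))
  expect_s3_class(pathway_table(), "clinic_pathway_table")
})

test_that("activity durations follow the stated central values", {
  set.seed(109)
  b <- sample_duration("biopsy", n = 1e5)
  expect_true(all(b %in% c(30, 45)))
  expect_lt(abs(mean(b) - 37.5), 4 * 7.5 / sqrt(1e5))

  u <- sample_duration("ultrasound", n = 1e5)
  expect_lt(abs(median(u) - 20), 0.1)
  expect_true(all(u > 0))
  expect_true(all(u >= 15 & u <= 25)) # +/-25% triangular support

  degenerate <- duration_model(dispersion = 0)
  expect_identical(
    sample_duration("initial_assessment", degenerate, n = 5), rep(10, 5)
  )
  expect_error(sample_duration("xray"), "recognised")
})
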