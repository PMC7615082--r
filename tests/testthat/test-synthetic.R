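test_that("cohort generation is byte-identical for a fixed seed", {
  params <- synthetic_params(n_patients = 30, visit_rate = 3,
                             codes_per_visit = 2,
                             learning_years_range = c(4, 6), seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(params, d1)
  generate_cohort(params, d2)
  for (f in c("events.csv", "outcomes.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty cohort writes header-only files", {
  params <- synthetic_params(n_patients = 0, seed = 1)
  d <- tempfile()
  generate_cohort(params, d)
  expect_equal(length(readLines(file.path(d, "events.csv"))), 1L)
  expect_equal(length(readLines(file.path(d, "outcomes.csv"))), 1L)
  unlink(d, recursive = TRUE)
})

test_that("prevalence follows the logistic model without a signal effect", {
  params <- synthetic_params(n_patients = 10000, visit_rate = 0.8,
                             codes_per_visit = 1,
                             learning_years_range = c(3.2, 4),
                             beta0 = -2, beta1 = 0, p_signal = 0,
                             seed = 21)
  g <- generate_cohort(params)
  p <- plogis(-2)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(g$truth$outcome) - p), 3 * se)
})

test_that("a saturated signal effect makes every carrier a case", {
  params <- synthetic_params(n_patients = 400, visit_rate = 2,
                             codes_per_visit = 2,
                             learning_years_range = c(4, 5),
                             signal_depth = "recent",
                             beta0 = -20, beta1 = 40, p_signal = 0.5,
                             seed = 31)
  g <- generate_cohort(params)
  expect_true(all(g$truth$outcome[g$truth$has_signal] == 1L))
  expect_true(all(g$truth$outcome[!g$truth$has_signal] == 0L))
})

test_that("visit counts match the renewal rate and records match params", {
  rate <- 5; yrs <- c(6, 6)
  params <- synthetic_params(n_patients = 2000, visit_rate = rate,
                             codes_per_visit = 3,
                             learning_years_range = yrs, p_signal = 0,
                             seed = 41)
  g <- generate_cohort(params)
  # mean record count ~ rate * years * codes/visit; the renewal boundary
  # contributes at most about one record of bias, added to the MC band
  cnt <- table(g$events$patient_id)
  expected <- rate * 6 * 3
  expect_lt(abs(mean(cnt) - expected),
            3 * sd(cnt) / sqrt(length(cnt)) + 1)
  # modality mix within Monte-Carlo tolerance
  frac <- table(g$events$modality) / nrow(g$events)
  for (m in names(params$modality_mix)) {
    p <- params$modality_mix[[m]]
    se <- sqrt(p * (1 - p) / nrow(g$events))
    expect_lt(abs(frac[[m]] - p), 4 * se)
  }
  # continuous values stay inside their binning ranges
  sch <- default_schemes()
  for (m in names(sch)) {
    v <- g$events$value[g$events$modality == m]
    expect_true(all(v >= sch[[m]]$lo & v <= sch[[m]]$hi))
  }
})

test_that("deep signals precede the newest-256 boundary for every carrier", {
  params <- synthetic_params(n_patients = 150, signal_depth = "deep",
                             min_records = 310, visit_rate = 8,
                             learning_years_range = c(8, 11), seed = 51)
  g <- generate_cohort(params)
  carriers <- g$truth$patient_id[g$truth$has_signal]
  expect_gt(length(carriers), 10)
  for (pid in carriers) {
    bl <- g$truth$baseline_date[g$truth$patient_id == pid]
    ev <- g$events[g$events$patient_id == pid & g$events$date < bl, ]
    m <- nrow(ev)
    ranks <- m - which(ev$code %in% params$signal_tokens) + 1L
    expect_equal(length(ranks), 6L)
    expect_true(all(ranks > 256))
    expect_true(all(ranks <= 512))  # within the hierarchical view
  }
  # generated cohorts pass full cohort validation
  co <- build_cohort(
    g$events, g$outcomes, "outcome", data_end = params$data_end,
    max_len = 512,
    baselines = data.frame(patient_id = g$truth$patient_id,
                           baseline_date = g$truth$baseline_date))
  expect_equal(length(co$examples), 150L)
})
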