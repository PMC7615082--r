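mk_history <- function(dates, codes, patient_id = "P1",
                       birth = as.Date("1960-01-01")) {
  patient_history(patient_id, birth,
                  data.frame(date = as.Date(dates), modality = "diagnosis",
                             code = codes, value = NA_real_,
                             stringsAsFactors = FALSE))
}

test_that("incident date is the earliest matching record", {
  h <- mk_history(c("2005-01-01", "2010-01-01", "2003-05-05"),
                  c("DIS", "DIS", "OTHER"))
  expect_equal(find_incident_date(h, "DIS"), as.Date("2005-01-01"))
  expect_true(is.na(find_incident_date(h, "NOPE")))
  h2 <- mk_history("2001-02-03", "DIS")
  expect_equal(find_incident_date(h2, c("DIS", "X")),
               as.Date("2001-02-03"))
})

test_that("case baselines fall 1-5 years before incident with >=3y history", {
  set.seed(1)
  incident <- as.Date("2010-06-01")
  for (i in 1:50) {
    b <- select_baseline_positive(incident, as.Date("1990-01-01"))
    expect_true(b >= add_years(incident, -5) && b <= add_years(incident, -1))
  }
  # history too short to allow any baseline
  expect_true(is.na(select_baseline_positive(incident,
                                             as.Date("2009-01-01"))))
  # partial window: lower bound from the 3-year learning constraint
  hs <- as.Date("2005-06-01")
  lo <- add_years(hs, 3)
  for (i in 1:50) {
    b <- select_baseline_positive(incident, hs)
    expect_true(b >= lo && b <= add_years(incident, -1))
  }
})

test_that("control baselines guarantee 3y learning and 5y follow-up", {
  set.seed(1)
  hs <- as.Date("2000-01-01"); de <- as.Date("2015-09-30")
  for (i in 1:50) {
    b <- select_baseline_negative(hs, de)
    expect_true(b >= add_years(hs, 3) && b <= add_years(de, -5))
  }
  expect_true(is.na(select_baseline_negative(as.Date("2008-01-01"), de)))
  # degenerate exactly-8-year span: the single feasible date
  hs8 <- as.Date("2007-09-30")
  b <- select_baseline_negative(hs8, add_years(hs8, 8))
  expect_equal(b, add_years(hs8, 3))
})

test_that("labels honour the one-year blanking and five-year horizon", {
  b <- as.Date("2008-01-01")
  fu <- add_years(b, 6)
  expect_equal(assign_label(add_years(b, 3), b, fu), 1L)       # in window
  expect_true(is.na(assign_label(add_years(b, 0.5), b, fu)))   # blanked
  expect_equal(assign_label(NA, b, fu), 0L)                    # event-free
  expect_true(is.na(assign_label(NA, b, add_years(b, 4))))     # short f/u
  expect_true(is.na(assign_label(b - 10, b, fu)))              # prevalent
  expect_equal(assign_label(add_years(b, 5), b, fu), 1L)       # boundary in
  expect_equal(assign_label(add_years(b, 5.1), b, fu), 0L)     # past window
})

test_that("encoding produces visit-alternating segments and positions", {
  ev <- data.frame(
    date = as.Date(c("2001-01-01", "2001-01-01", "2001-03-01")),
    modality = "diagnosis", code = c("A", "B", "C"), value = NA_real_)
  h <- patient_history("P1", as.Date("1950-06-15"), ev)
  vocab <- build_vocab(c("A", "B", "C"))
  enc <- encode_history(h, as.Date("2004-01-01"), vocab, max_len = 8)
  expect_equal(enc$segment_ids[1:3], c(0L, 0L, 1L))
  expect_equal(enc$position_ids[1:3], c(0L, 0L, 1L))
  expect_equal(enc$attention_mask, c(1L, 1L, 1L, rep(0L, 5)))
  expect_equal(enc$token_ids[4:8], rep(1L, 5))  # PAD
  expect_equal(enc$age_ids[1:3], c(50L, 50L, 50L))
  expect_equal(enc$true_length, 3L)
  expect_equal(decode_sequence(enc, vocab), c("A", "B", "C"))
})

test_that("truncation keeps the latest records and ehr_length the full count", {
  n <- 30
  ev <- data.frame(date = as.Date("2000-01-01") + seq_len(n) * 10,
                   modality = "diagnosis", code = sprintf("C%02d", seq_len(n)),
                   value = NA_real_)
  h <- patient_history("P1", as.Date("1950-01-01"), ev)
  vocab <- build_vocab(ev$code)
  enc <- encode_history(h, as.Date("2002-01-01"), vocab, max_len = 12)
  expect_equal(enc$ehr_length, n)
  expect_equal(enc$true_length, 12L)
  # first kept record is the (n - 12 + 1)-th oldest
  expect_equal(decode_sequence(enc, vocab), sprintf("C%02d", 19:30))
  # positions restart at 0 for the kept window and stay monotone
  expect_equal(enc$position_ids[1], 0L)
  expect_true(all(diff(enc$position_ids[1:12]) >= 0))
  expect_true(all(diff(enc$age_ids[1:12]) >= 0))
})

test_that("encoding drops out-of-range measurements and maps unseen to UNK", {
  ev <- data.frame(
    date = as.Date(c("2001-01-01", "2001-02-01", "2001-03-01")),
    modality = c("systolic_bp", "systolic_bp", "diagnosis"),
    code = c(NA, NA, "NEW"), value = c(92, 300, NA))
  h <- patient_history("P1", as.Date("1950-01-01"), ev)
  vocab <- build_vocab("SBP_90_95")
  enc <- encode_history(h, as.Date("2004-01-01"), vocab, max_len = 6)
  expect_equal(enc$ehr_length, 2L)  # the 300 mmHg reading is dropped
  expect_equal(decode_sequence(enc, vocab), c("SBP_90_95", "UNK"))
  expect_error(encode_history(h, as.Date("2000-01-01"), vocab, 6), "empty")
})

test_that("built cohorts keep labels consistent with known incident dates", {
  sc <- small_cohort()
  tab <- sc$cohort$table
  truth <- sc$gen$truth
  m <- merge(tab, truth, by = "patient_id")
  expect_gt(nrow(m), 50)
  for (i in seq_len(nrow(m))) {
    if (m$label[i] == 1L) {
      dt <- years_between(m$baseline_date.x[i], m$incident_date[i])
      expect_true(dt > 1 - 1e-9 && dt <= 5 + 1e-9)
    } else {
      expect_true(is.na(m$incident_date[i]) ||
                    years_between(m$baseline_date.x[i],
                                  m$incident_date[i]) > 5 - 1e-2)
    }
  }
  # every encoded sequence is monotone in age and position
  for (e in sc$cohort$examples[1:20]) {
    n <- e$encoded$true_length
    expect_true(all(diff(e$encoded$age_ids[1:n]) >= 0))
    expect_true(all(diff(e$encoded$position_ids[1:n]) >= 0))
    expect_true(all(e$encoded$segment_ids[1:n] %in% 0:1))
  }
})
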