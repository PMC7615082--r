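# Seeded generator of multimodal longitudinal EHR cohorts.  Visits follow a
# gamma renewal process (shape 2: overdispersed gaps, long right tail of
# record counts); each visit carries a Poisson number of records with
# modalities drawn from a configurable mix.  A binary risk signal (a small
# set of dedicated tokens) can be planted either among the most recent
# records or strictly deeper than the newest 256 records of the learning
# period, and the outcome follows a logistic model on signal carriage --
# matching the fixed-window binary endpoint of the labelling rules exactly.

SMOKING_TOKENS <- paste0("SMOKE_", c("current", "ex", "non"))
DRINKING_TOKENS <- paste0("DRINK_", c("current", "ex", "non"))

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate a primary-care cohort with long histories: ~9 visits per
#' year over a 9-13 year learning period, ~4.4 records per visit (so a mean
#' learning-period length of roughly 400 records, with a substantial
#' fraction beyond 256), a modality mix dominated by medications and tests,
#' and a planted long-range signal carried by 20% of patients that raises
#' the outcome probability from ~3% to ~38% (cohort prevalence ~10%).
#'
#' @param n_patients number of patients
#' @param visit_rate mean visits per year (gamma renewal, shape 2)
#' @param codes_per_visit Poisson mean records per visit
#' @param modality_mix named probability vector over modalities
#' @param vocab_sizes named integer vector: token counts for the categorical
#'   coded modalities (diagnosis/medication/procedure/test)
#' @param signal_tokens dedicated diagnosis-modality tokens carried by
#'   signal-positive patients
#' @param signal_copies how many records of each signal token are planted
#' @param signal_depth `"recent"` (within the newest 200 records) or
#'   `"deep"` (strictly older than the newest 256 records)
#' @param p_signal probability a patient carries the signal
#' @param beta0 baseline log-odds of the outcome
#' @param beta1 additive log-odds effect of signal carriage
#' @param learning_years_range min/max years of learning period per patient
#' @param baseline_jitter_years baseline date spread before `data_end - 5y`
#' @param data_end end of data coverage
#' @param age_at_start_range min/max age (years) at the first record
#' @param min_records when positive, resample the visit process until the
#'   learning period holds at least this many records (gives every patient a
#'   long history, e.g. for experiments in the long-EHR regime)
#' @param seed integer seed
#' @return a `synthetic_params` list
#' @export
synthetic_params <- function(n_patients = 5000,
                             visit_rate = 9,
                             codes_per_visit = 4.4,
                             modality_mix = c(diagnosis = 0.08,
                                              medication = 0.40,
                                              procedure = 0.02,
                                              test = 0.33,
                                              systolic_bp = 0.033,
                                              diastolic_bp = 0.033,
                                              bmi = 0.012,
                                              smoking = 0.08,
                                              drinking = 0.012),
                             vocab_sizes = c(diagnosis = 200,
                                             medication = 150,
                                             procedure = 80,
                                             test = 120),
                             signal_tokens = c("SIG_A", "SIG_B", "SIG_C"),
                             signal_copies = 2,
                             signal_depth = c("deep", "recent"),
                             p_signal = 0.2,
                             beta0 = -3.48,
                             beta1 = 3.0,
                             learning_years_range = c(9, 13),
                             baseline_jitter_years = 2,
                             data_end = as.Date("2015-09-30"),
                             age_at_start_range = c(30, 70),
                             min_records = 0L,
                             seed = 1L) {
  signal_depth <- match.arg(signal_depth)
  mix <- modality_mix / sum(modality_mix)
  stopifnot(all(names(mix) %in% MODALITIES), visit_rate > 0,
            codes_per_visit > 0, p_signal >= 0, p_signal <= 1)
  structure(list(n_patients = n_patients, visit_rate = visit_rate,
                 codes_per_visit = codes_per_visit, modality_mix = mix,
                 vocab_sizes = vocab_sizes, signal_tokens = signal_tokens,
                 signal_copies = signal_copies, signal_depth = signal_depth,
                 p_signal = p_signal, beta0 = beta0, beta1 = beta1,
                 learning_years_range = learning_years_range,
                 baseline_jitter_years = baseline_jitter_years,
                 data_end = as.Date(data_end),
                 age_at_start_range = age_at_start_range,
                 min_records = min_records,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# draw one categorical code for each element of `mods`
draw_codes <- function(mods, params) {
  schemes <- default_schemes()
  code <- rep(NA_character_, length(mods))
  value <- rep(NA_real_, length(mods))
  for (m in unique(mods)) {
    i <- which(mods == m)
    if (m %in% VALUE_MODALITIES) {
      sc <- schemes[[m]]
      value[i] <- stats::runif(length(i), sc$lo, sc$hi)
    } else if (m == "smoking") {
      code[i] <- sample(SMOKING_TOKENS, length(i), replace = TRUE)
    } else if (m == "drinking") {
      code[i] <- sample(DRINKING_TOKENS, length(i), replace = TRUE)
    } else {
      code[i] <- paste0(toupper(substr(m, 1, 4)), "_",
                        sample.int(params$vocab_sizes[[m]], length(i),
                                   replace = TRUE))
    }
  }
  list(code = code, value = value)
}

#' Generate one synthetic patient
#'
#' @param params a [synthetic_params()] list
#' @param patient_id identifier for the generated patient
#' @return list with `events` (data.frame rows for the events file),
#'   `truth` (one-row data.frame: `patient_id`, `has_signal`,
#'   `linear_predictor`, `outcome`, `incident_date`, `baseline_date`,
#'   `birth_date`, `n_records`)
#' @export
generate_patient <- function(params, patient_id = "P1") {
  learn_years <- stats::runif(1, params$learning_years_range[1],
                              params$learning_years_range[2])
  baseline <- add_years(params$data_end, -5) -
    round(stats::runif(1, 0, params$baseline_jitter_years) * DAYS_PER_YEAR)
  start <- add_years(baseline, -learn_years)
  birth <- add_years(start, -stats::runif(1, params$age_at_start_range[1],
                                          params$age_at_start_range[2]))
  has_signal <- stats::runif(1) < params$p_signal
  depth_min <- if (params$signal_depth == "deep") 262L else 1L

  n_sig <- length(params$signal_tokens) * params$signal_copies
  need <- max(params$min_records,
              if (has_signal) depth_min + n_sig + 20L else 0L)
  for (attempt in 1:25) {
    # gamma renewal visit process over the learning period
    n_gap <- ceiling(learn_years * params$visit_rate * 2) + 10
    gaps <- stats::rgamma(n_gap, shape = 2, rate = 2 * params$visit_rate)
    at <- cumsum(gaps)
    at <- at[at < learn_years]
    visit_dates <- start + round(at * DAYS_PER_YEAR)
    visit_dates <- visit_dates[visit_dates < baseline]
    n_per_visit <- stats::rpois(length(visit_dates), params$codes_per_visit)
    m <- sum(n_per_visit)
    if (m >= need) break
  }
  dates <- rep(visit_dates, n_per_visit)
  mods <- sample(names(params$modality_mix), m, replace = TRUE,
                 prob = params$modality_mix)
  cv <- draw_codes(mods, params)
  ev <- data.frame(patient_id = rep(patient_id, m), date = dates,
                   modality = mods, code = cv$code, value = cv$value,
                   stringsAsFactors = FALSE)

  if (has_signal && m > n_sig) {
    # ranks counted from the most recent record; "deep" plants the signal
    # strictly older than the newest-256 boundary but still within reach of
    # a 512-record hierarchical view
    hi <- if (params$signal_depth == "deep") min(m - 1L, 480L)
          else min(m, 200L)
    lo <- min(depth_min, hi)
    ranks <- sample(seq.int(lo, hi),
                    min(n_sig, hi - lo + 1L), replace = FALSE)
    idx <- m - ranks + 1L
    sig <- data.frame(patient_id = patient_id, date = dates[idx],
                      modality = "diagnosis",
                      code = rep_len(params$signal_tokens, length(idx)),
                      value = NA_real_, stringsAsFactors = FALSE)
    ev <- rbind(ev, sig)
    ev <- ev[order(ev$date), , drop = FALSE]  # stable: ties keep file order
  }

  lp <- params$beta0 + params$beta1 * as.numeric(has_signal)
  outcome <- stats::runif(1) < stats::plogis(lp)
  incident <- if (outcome)
    baseline + sample(366:1826, 1) else as.Date(NA)

  ev$birth_date <- rep(birth, nrow(ev))
  list(events = ev,
       truth = data.frame(patient_id = patient_id,
                          has_signal = has_signal,
                          linear_predictor = lp,
                          outcome = as.integer(outcome),
                          incident_date = incident,
                          baseline_date = baseline,
                          birth_date = birth,
                          n_records = nrow(ev),
                          stringsAsFactors = FALSE))
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `params$seed`: the same parameters reproduce
#' byte-identical files.
#'
#' @param params a [synthetic_params()] list
#' @param out_dir optional directory; when given, writes `events.csv`,
#'   `outcomes.csv`, and `truth.csv`
#' @return list with data.frames `events`, `outcomes` (patient_id, disease,
#'   incident_date), and `truth`
#' @export
generate_cohort <- function(params, out_dir = NULL) {
  set.seed(params$seed)
  evs <- vector("list", params$n_patients)
  trs <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    g <- generate_patient(params, sprintf("P%05d", i))
    evs[[i]] <- g$events
    trs[[i]] <- g$truth
  }
  events <- as.data.frame(data.table::rbindlist(evs))
  truth <- as.data.frame(data.table::rbindlist(trs))
  if (!nrow(events) && !ncol(events))
    events <- data.frame(patient_id = character(), date = as.Date(character()),
                         modality = character(), code = character(),
                         value = numeric(), birth_date = as.Date(character()))
  if (!nrow(truth) && !ncol(truth))
    truth <- data.frame(patient_id = character(), has_signal = logical(),
                        linear_predictor = numeric(), outcome = integer(),
                        incident_date = as.Date(character()),
                        baseline_date = as.Date(character()),
                        birth_date = as.Date(character()),
                        n_records = integer())
  pos <- truth[truth$outcome == 1L, , drop = FALSE]
  outcomes <- data.frame(patient_id = pos$patient_id,
                         disease = rep("outcome", nrow(pos)),
                         incident_date = pos$incident_date,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(events, file.path(out_dir, "events.csv"))
    data.table::fwrite(outcomes, file.path(out_dir, "outcomes.csv"))
    data.table::fwrite(truth, file.path(out_dir, "truth.csv"))
  }
  invisible(list(events = events, outcomes = outcomes, truth = truth))
}
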