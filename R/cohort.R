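# Cohort construction: patient histories, incident dates, baseline-date
# selection, 5-year labelling, and encoding of learning-period records into
# model-ready sequences.
#
# Study design implemented here: all records strictly before a per-patient
# baseline date form the learning period; the label is the incidence of the
# outcome within (baseline + 1y, baseline + 5y].  Cases get a baseline
# sampled uniformly 1-5 years before their incident date; event-free
# patients get a baseline guaranteeing >= 5 years of follow-up.  Patients
# with < 3 years of records before baseline are ineligible.

MODALITIES <- c("diagnosis", "medication", "procedure", "test",
                "systolic_bp", "diastolic_bp", "bmi", "smoking", "drinking")
VALUE_MODALITIES <- c("systolic_bp", "diastolic_bp", "bmi")

#' Construct a patient history
#'
#' @param patient_id opaque identifier
#' @param birth_date `Date`
#' @param events data.frame with columns `date`, `modality`, and `code` or
#'   `value`; sorted stably by date
#' @param incident_dates optional named list/vector of first-occurrence dates
#'   per disease
#' @return a `patient_history` object
#' @export
patient_history <- function(patient_id, birth_date, events,
                            incident_dates = NULL) {
  stopifnot(all(events$modality %in% MODALITIES))
  events <- events[order(events$date), , drop = FALSE]  # stable sort
  if (nrow(events) && any(as.Date(events$date) < as.Date(birth_date)))
    stop("event dates must not precede birth_date")
  has_val <- events$modality %in% VALUE_MODALITIES
  if (any(has_val & !is.finite(suppressWarnings(as.numeric(events$value)))))
    stop("value-bearing modalities require a numeric value")
  if (any(!has_val & (is.na(events$code) | events$code == "")))
    stop("categorical modalities require a code")
  structure(list(patient_id = patient_id,
                 birth_date = as.Date(birth_date),
                 events = events,
                 incident_dates = incident_dates),
            class = "patient_history")
}

#' First occurrence date of any code in a code set
#'
#' @param history a [patient_history()]
#' @param code_set non-empty character vector of disease-defining codes
#' @return the earliest matching event `Date`, or `NA` if none
#' @export
find_incident_date <- function(history, code_set) {
  stopifnot(length(code_set) > 0)
  hit <- !is.na(history$events$code) & history$events$code %in% code_set
  if (!any(hit)) return(as.Date(NA))
  min(as.Date(history$events$date)[hit])
}

#' Sample a baseline date for a case
#'
#' Uniform over days in `[incident - 5y, incident - 1y]` intersected with
#' dates at least 3 years after the start of the record history; `NA`
#' (ineligible) when the intersection is empty.
#'
#' @param incident incident `Date`
#' @param history_start first record `Date`
#' @return a `Date`, or `NA` if no eligible baseline exists
#' @export
select_baseline_positive <- function(incident, history_start) {
  lo <- max(add_years(incident, -5), add_years(history_start, 3))
  hi <- add_years(incident, -1)
  if (lo > hi) return(as.Date(NA))
  lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
}

#' Sample a baseline date for an event-free patient
#'
#' Uniform over days in `[history_start + 3y, data_end - 5y]` so that at
#' least 3 years of learning period precede and 5 years of follow-up succeed
#' the baseline; `NA` (ineligible) when the window is empty.
#'
#' @param history_start first record `Date`
#' @param data_end end of data coverage (`Date`)
#' @return a `Date`, or `NA` if no eligible baseline exists
#' @export
select_baseline_negative <- function(history_start, data_end) {
  lo <- add_years(history_start, 3)
  hi <- add_years(data_end, -5)
  if (lo > hi) return(as.Date(NA))
  lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
}

#' Assign the 5-year outcome label for a chosen baseline
#'
#' Events in the year right after baseline are ignored (recording-lag
#' blanking): an incident in `(baseline, baseline + 1y]` excludes the
#' patient.  An incident in `(baseline + 1y, baseline + 5y]` labels 1.  With
#' no incident in `(baseline, baseline + 5y]`, the patient labels 0 provided
#' follow-up covers `baseline + 5y`, and is excluded otherwise.  A prevalent
#' case (incident on or before baseline) is excluded.
#'
#' @param incident incident `Date` or `NA` if never observed
#' @param baseline baseline `Date`
#' @param followup_end last `Date` of data coverage for the patient
#' @return `1L`, `0L`, or `NA_integer_` (exclude)
#' @export
assign_label <- function(incident, baseline, followup_end) {
  if (!is.na(incident)) {
    if (incident <= baseline) return(NA_integer_)
    t <- years_between(baseline, incident)
    if (t <= 1) return(NA_integer_)
    if (t <= 5) return(1L)
  }
  if (years_between(baseline, followup_end) >= 5) 0L else NA_integer_
}

## ---- sequence encoding ---------------------------------------------------

AGE_MAX <- 110L

# tokens for the learning period of a history: categorical codes kept as-is,
# continuous values binned (rejected values dropped); returns data.frame
learning_tokens <- function(history, baseline, schemes) {
  ev <- history$events[as.Date(history$events$date) < as.Date(baseline), ,
                       drop = FALSE]
  if (!nrow(ev))
    return(data.frame(date = as.Date(character()), token = character(),
                      modality = character()))
  tok <- as.character(ev$code)
  for (m in intersect(unique(ev$modality), VALUE_MODALITIES)) {
    i <- ev$modality == m
    if (is.null(schemes[[m]]))
      stop("no binning scheme for modality ", m)
    tok[i] <- bin_value(as.numeric(ev$value[i]), schemes[[m]])
  }
  keep <- !is.na(tok)
  data.frame(date = as.Date(ev$date)[keep], token = tok[keep],
             modality = ev$modality[keep], stringsAsFactors = FALSE)
}

#' Encode the learning period of one patient into a model-ready sequence
#'
#' Keeps events strictly before `baseline`, bins continuous measurements
#' (dropping out-of-range readings), maps tokens to vocabulary ids (`UNK`
#' for unseen), computes per-event age in completed years, visit-alternating
#' segment ids and per-visit position ids (all records sharing a calendar
#' date form one visit), keeps the *latest* `max_len` records when longer,
#' and right-pads with `PAD` (attention mask 0).
#'
#' @param history a [patient_history()]
#' @param baseline baseline `Date`
#' @param vocab a [build_vocab()] vocabulary
#' @param max_len maximum encoded length
#' @param schemes named list of [binning_scheme()]s for value modalities
#' @return an `encoded_sequence`: list with integer vectors `token_ids`,
#'   `age_ids`, `segment_ids`, `position_ids`, `attention_mask` (all length
#'   `max_len`), `true_length`, and `ehr_length` (record count before
#'   truncation)
#' @export
encode_history <- function(history, baseline, vocab, max_len,
                           schemes = default_schemes()) {
  lt <- learning_tokens(history, baseline, schemes)
  ehr_length <- nrow(lt)
  if (ehr_length == 0) stop("empty learning period for patient ",
                            history$patient_id)
  if (ehr_length > max_len)
    lt <- lt[(ehr_length - max_len + 1):ehr_length, , drop = FALSE]
  n <- nrow(lt)
  ids <- vocab_encode(vocab, lt$token)
  ages <- pmin(pmax(age_at(history$birth_date, lt$date), 0L), AGE_MAX)
  visit <- match(as.integer(lt$date), unique(as.integer(lt$date))) - 1L
  pad <- max_len - n
  pad_id <- RESERVED_TOKENS[["PAD"]]
  structure(list(
    token_ids = c(ids, rep(pad_id, pad)),
    age_ids = as.integer(c(ages, rep(0L, pad))),
    segment_ids = as.integer(c(visit %% 2L, rep(0L, pad))),
    position_ids = as.integer(c(visit, rep(0L, pad))),
    attention_mask = c(rep(1L, n), rep(0L, pad)),
    true_length = n,
    ehr_length = ehr_length), class = "encoded_sequence")
}

#' Recover the kept token strings of an encoded sequence
#' @param encoded an [encode_history()] result
#' @param vocab the vocabulary used to encode
#' @return character vector of length `true_length`
#' @export
decode_sequence <- function(encoded, vocab) {
  vocab_decode(vocab, encoded$token_ids[seq_len(encoded$true_length)])
}

#' Build a labelled cohort from event, outcome, and patient tables
#'
#' For each patient: locate the incident date of `disease` (from the
#' outcomes table), sample a baseline date (cases: 1-5 years before
#' incident; event-free: with 5 years of guaranteed follow-up; both with a
#' 3-year minimum learning period), assign the 5-year label, and encode the
#' learning period.  Ineligible or excluded patients are dropped.
#'
#' @param events data.frame: `patient_id`, `date`, `modality`, `code`,
#'   `value`, and `birth_date` (constant within patient)
#' @param outcomes data.frame: `patient_id`, `disease`, `incident_date`
#' @param disease outcome to model (must match `outcomes$disease`)
#' @param data_end end of data coverage (`Date`); defaults to the latest
#'   event date
#' @param vocab vocabulary; defaults to one built from the encoded tokens of
#'   `events`
#' @param max_len maximum encoded sequence length
#' @param schemes binning schemes for value modalities
#' @param baselines optional data.frame `patient_id`, `baseline_date`: use
#'   these baselines instead of sampling (e.g. the generator's own)
#' @param seed optional integer seed for baseline sampling
#' @return list with `examples` (list of cohort examples: `encoded`,
#'   `label`, `baseline_date`, `ehr_length`, `patient_id`), `vocab`, and
#'   `table` (one summary row per emitted example)
#' @export
build_cohort <- function(events, outcomes, disease, data_end = NULL,
                         vocab = NULL, max_len = 512,
                         schemes = default_schemes(), baselines = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  events$date <- as.Date(events$date)
  if (is.null(data_end)) data_end <- max(events$date)
  data_end <- as.Date(data_end)
  if (is.null(vocab)) vocab <- cohort_vocab(events, schemes)
  oc <- outcomes[outcomes$disease == disease, , drop = FALSE]
  inc_map <- stats::setNames(as.Date(oc$incident_date), oc$patient_id)
  base_map <- if (!is.null(baselines))
    stats::setNames(as.Date(baselines$baseline_date), baselines$patient_id)
  ev_split <- split(events, events$patient_id)

  examples <- list()
  rows <- list()
  for (pid in names(ev_split)) {
    ev <- ev_split[[pid]]
    hist <- patient_history(pid, ev$birth_date[1], ev)
    incident <- if (pid %in% names(inc_map)) inc_map[[pid]] else as.Date(NA)
    baseline <- if (!is.null(base_map)) {
      if (pid %in% names(base_map)) base_map[[pid]] else as.Date(NA)
    } else if (!is.na(incident)) {
      select_baseline_positive(incident, min(ev$date))
    } else {
      select_baseline_negative(min(ev$date), data_end)
    }
    if (is.na(baseline)) next
    if (years_between(min(ev$date), baseline) < 3) next
    label <- assign_label(incident, baseline, data_end)
    if (is.na(label)) next
    enc <- tryCatch(encode_history(hist, baseline, vocab, max_len, schemes),
                    error = function(e) NULL)
    if (is.null(enc)) next
    examples[[length(examples) + 1L]] <-
      list(encoded = enc, label = label, baseline_date = baseline,
           ehr_length = enc$ehr_length, patient_id = pid)
    rows[[length(rows) + 1L]] <-
      data.frame(patient_id = pid, label = label,
                 baseline_date = baseline, ehr_length = enc$ehr_length,
                 stringsAsFactors = FALSE)
  }
  list(examples = examples, vocab = vocab,
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(patient_id = character(), label = integer(),
                    baseline_date = as.Date(character()),
                    ehr_length = integer()))
}

#' Vocabulary covering all tokens an event table can produce
#'
#' Categorical codes observed in the data plus every bin token of the given
#' schemes (so unseen-but-valid measurement bins encode consistently).
#'
#' @param events events data.frame (see [build_cohort()])
#' @param schemes binning schemes
#' @return a [build_vocab()] vocabulary
#' @export
cohort_vocab <- function(events, schemes = default_schemes()) {
  cat_tok <- unique(events$code[!(events$modality %in% VALUE_MODALITIES)])
  cat_tok <- cat_tok[!is.na(cat_tok) & cat_tok != ""]
  build_vocab(c(cat_tok, unlist(lapply(schemes, bin_tokens),
                                use.names = FALSE)))
}
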