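# Shared fixtures: tiny encoded examples, miniature model configurations,
# and a small synthetic cohort builder used across test files.

# a hand-built encoded example with n real records spread over a few visits
tiny_example <- function(n, max_len = 16, vocab_hi = 12, seed = NULL,
                         label = 0L) {
  if (!is.null(seed)) set.seed(seed)
  tok <- sample(5:vocab_hi, n, replace = TRUE)
  visit <- sort(sample(0:max(1, n %/% 3), n, replace = TRUE))
  visit <- match(visit, unique(visit)) - 1L
  pad <- max_len - n
  enc <- structure(list(
    token_ids = as.integer(c(tok, rep(1L, pad))),
    age_ids = as.integer(c(sort(sample(40:60, n, TRUE)), rep(0L, pad))),
    segment_ids = as.integer(c(visit %% 2L, rep(0L, pad))),
    position_ids = as.integer(c(visit, rep(0L, pad))),
    attention_mask = as.integer(c(rep(1L, n), rep(0L, pad))),
    true_length = as.integer(n), ehr_length = as.integer(n)),
    class = "encoded_sequence")
  list(encoded = enc, label = as.integer(label), ehr_length = as.integer(n),
       patient_id = paste0("T", n))
}

tiny_hier_config <- function(max_len = 16) {
  hier_config(d = 8, n_heads = 2, d_ff = 12, extractor_layers = 2,
              aggregator_layers = 2, window = 4, stride = 2,
              max_len = max_len, dropout = 0, attn_dropout = 0)
}

tiny_flat_config <- function(max_len = 12) {
  flat_config(d = 8, n_heads = 2, d_ff = 12, n_layers = 2,
              max_len = max_len, dropout = 0, attn_dropout = 0)
}

# small synthetic cohort (generated once per test run, cached in the
# test environment)
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(small_cohort_cache$co)) {
    params <- synthetic_params(n_patients = 120, visit_rate = 4,
                               codes_per_visit = 3,
                               learning_years_range = c(4, 8),
                               signal_depth = "recent", seed = 42)
    g <- generate_cohort(params)
    co <- build_cohort(
      g$events, g$outcomes, "outcome", data_end = params$data_end,
      max_len = 256,
      baselines = data.frame(patient_id = g$truth$patient_id,
                             baseline_date = g$truth$baseline_date))
    small_cohort_cache$co <- list(gen = g, cohort = co, params = params)
  }
  small_cohort_cache$co
}

# brute-force metric oracles
auroc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

auprc_brute <- function(labels, scores) {
  # walk all distinct thresholds from high to low, step interpolation
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
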