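# Evaluation protocols: EHR-length subgroup analysis with positive-rate
# matching, training-fraction curves with and without pre-training, and
# modality ablation.

#' Length-subgroup evaluation with positive-rate-matched bootstrap
#'
#' Splits examples at `threshold` learning-period records, reports metrics
#' for (a) the short subgroup, (b) the long subgroup, and (c) the long
#' subgroup with all negatives kept and positives subsampled without
#' replacement to match the short subgroup's positive rate, averaged over
#' `n_boot` draws.
#'
#' @param examples list of cohort examples with labels and `ehr_length`
#' @param model a trained model, or `NULL` when `scores` is given
#' @param scores optional precomputed risk scores aligned with `examples`
#' @param threshold EHR-length split point
#' @param n_boot bootstrap repetitions for report (c)
#' @param seed integer seed for the bootstrap draws
#' @return data.frame of [eval_report()] rows, subgroups
#'   `short`, `long`, `long_rate_matched`; (c) is `NA` (infeasible) when
#'   the long subgroup's positive rate is below the short subgroup's
#' @export
subgroup_eval <- function(examples, model = NULL, scores = NULL,
                          threshold = 256, n_boot = 5, seed = 1L) {
  if (is.null(scores)) scores <- predict_risk(model, examples)
  len <- vapply(examples, function(e) as.integer(e$ehr_length), 1L)
  y <- vapply(examples, function(e) as.integer(e$label), 1L)
  short <- len <= threshold
  long <- !short
  if (!any(short) || !any(long))
    stop("both length subgroups must be non-empty")
  rep_a <- eval_report(y[short], scores[short], "short")
  rep_b <- eval_report(y[long], scores[long], "long")

  rate_short <- mean(y[short])
  long_pos <- which(long & y == 1)
  long_neg <- which(long & y == 0)
  k <- round(rate_short / (1 - rate_short) * length(long_neg))
  if (k > length(long_pos) || k < 1) {
    rep_c <- data.frame(subgroup = "long_rate_matched", n = NA_integer_,
                        n_pos = NA_integer_, auroc = NA_real_,
                        auprc = NA_real_, stringsAsFactors = FALSE)
  } else {
    set.seed(seed)
    reps <- lapply(seq_len(n_boot), function(i) {
      keep <- c(sample(long_pos, k), long_neg)
      eval_report(y[keep], scores[keep], "long_rate_matched")
    })
    rep_c <- reps[[1]]
    rep_c$auroc <- mean(vapply(reps, function(r) r$auroc, 1))
    rep_c$auprc <- mean(vapply(reps, function(r) r$auprc, 1))
    rep_c$n <- k + length(long_neg)
    rep_c$n_pos <- k
  }
  rbind(rep_a, rep_b, rep_c)
}

#' Training-fraction learning curves
#'
#' For each fraction, subsamples the training set without replacement,
#' trains from scratch (and, when a pre-trained state is given, from the
#' pre-trained encoder), evaluates on the fixed validation set, and
#' averages metrics over seeds.
#'
#' @param train_examples,val_examples cohort example lists
#' @param model_factory function(seed) returning a freshly initialized
#'   model
#' @param fractions training-set fractions in (0, 1]
#' @param n_seeds runs per fraction
#' @param pretrained optional [init_byol()] state whose encoder warm-starts
#'   a second arm of the curve
#' @param epochs,batch_size,peak_lr training options
#' @param seed base seed
#' @return data.frame: fraction, arm (`scratch`/`pretrained`), n_train,
#'   auroc, auprc (seed-averaged)
#' @export
fraction_curve <- function(train_examples, val_examples, model_factory,
                           fractions = c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0),
                           n_seeds = 3, pretrained = NULL, epochs = 3,
                           batch_size = 32, peak_lr = 5e-4, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  vy <- vapply(val_examples, function(e) as.integer(e$label), 1L)
  y <- vapply(train_examples, function(e) as.integer(e$label), 1L)
  out <- list()
  for (f in fractions) {
    m_auc <- m_pr <- c(scratch = 0, pretrained = 0)
    cnt <- 0
    n_take <- max(1, round(f * length(train_examples)))
    for (s in seq_len(n_seeds)) {
      set.seed(seed + 1000L * s)
      idx <- if (f >= 1) seq_along(train_examples) else
        sample(length(train_examples), n_take)
      if (sum(y[idx]) < 1) {
        warning(sprintf("fraction %.3f seed %d: no positives, skipped",
                        f, s))
        next
      }
      sub <- train_examples[idx]
      arms <- list(scratch = model_factory(seed + s))
      if (!is.null(pretrained))
        arms$pretrained <- byol_to_model(pretrained, seed = seed + s)
      for (arm in names(arms)) {
        tr <- train_model(arms[[arm]], sub, val_examples, epochs = epochs,
                          batch_size = batch_size, peak_lr = peak_lr,
                          seed = seed + s)
        p <- predict_risk(tr$model, val_examples)
        m_auc[arm] <- m_auc[arm] + auroc(vy, p)
        m_pr[arm] <- m_pr[arm] + auprc(vy, p)
      }
      cnt <- cnt + 1
    }
    if (cnt == 0) next
    arms_used <- if (is.null(pretrained)) "scratch" else
      c("scratch", "pretrained")
    for (arm in arms_used)
      out[[length(out) + 1L]] <-
        data.frame(fraction = f, arm = arm, n_train = n_take,
                   auroc = m_auc[[arm]] / cnt, auprc = m_pr[[arm]] / cnt,
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Modality ablation
#'
#' Starting from a base modality set (diagnosis + medication by default),
#' adds one further modality at a time, drops all records of the excluded
#' modalities before encoding, and trains/evaluates identically per
#' setting.  With `eval_only = TRUE` a fixed `model` is evaluated on the
#' re-encoded cohorts instead of retraining.
#'
#' @param events,outcomes,disease,baselines cohort inputs (see
#'   [build_cohort()]); `baselines` fixes the per-patient baseline dates so
#'   every setting encodes the same learning periods
#' @param vocab shared vocabulary (built on all modalities)
#' @param split function(table) returning list(train, val) index vectors,
#'   or `NULL` for a deterministic 80/20 split
#' @param base base modality set
#' @param add_one_of modalities to add one at a time
#' @param model_factory function(seed) returning a fresh model (ignored
#'   when `eval_only`)
#' @param model fixed model for `eval_only` mode
#' @param eval_only logical
#' @param data_end end of data coverage (`Date`); forwarded to
#'   [build_cohort()]
#' @param max_len,epochs,batch_size,peak_lr,seed options
#' @return data.frame: setting, modalities, auroc, auprc
#' @export
modality_ablation <- function(events, outcomes, disease, baselines, vocab,
                              model_factory = NULL, model = NULL,
                              base = c("diagnosis", "medication"),
                              add_one_of = setdiff(MODALITIES, base),
                              eval_only = FALSE, data_end = NULL,
                              max_len = 512,
                              split = NULL, epochs = 3, batch_size = 32,
                              peak_lr = 5e-4, seed = 1L) {
  settings <- c(list(base = base),
                stats::setNames(lapply(add_one_of, function(m) c(base, m)),
                                paste0("base+", add_one_of)))
  out <- list()
  for (nm in names(settings)) {
    mods <- settings[[nm]]
    ev <- events[events$modality %in% mods, , drop = FALSE]
    co <- build_cohort(ev, outcomes, disease, data_end = data_end,
                       vocab = vocab, max_len = max_len,
                       baselines = baselines, seed = seed)
    y <- vapply(co$examples, function(e) as.integer(e$label), 1L)
    if (eval_only) {
      p <- predict_risk(model, co$examples)
      a <- auroc(y, p); pr <- auprc(y, p)
    } else {
      idx <- if (is.null(split)) {
        n <- length(co$examples)
        list(train = seq_len(floor(0.8 * n)),
             val = seq.int(floor(0.8 * n) + 1L, n))
      } else split(co$table)
      tr <- train_model(model_factory(seed), co$examples[idx$train],
                        co$examples[idx$val], epochs = epochs,
                        batch_size = batch_size, peak_lr = peak_lr,
                        seed = seed)
      p <- predict_risk(tr$model, co$examples[idx$val])
      a <- auroc(y[idx$val], p); pr <- auprc(y[idx$val], p)
    }
    out[[nm]] <- data.frame(setting = nm,
                            modalities = paste(mods, collapse = "+"),
                            auroc = a, auprc = pr,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
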