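test_that("three-stage schedule hits its landmarks and stays continuous", {
  cfg <- schedule_config(peak_lr = 1e-4)
  N <- 1000
  expect_equal(lr_at(0, N, cfg), 0)
  expect_equal(lr_at(100, N, cfg), 1e-4)  # warm-up end
  expect_equal(lr_at(500, N, cfg), 1e-4)  # hold end
  expect_equal(lr_at(N, N, cfg), 0)       # cosine lands at zero
  expect_equal(lr_at(750, N, cfg), 1e-4 * 0.5 * (1 + cos(pi / 2)))
  # continuity at both stage boundaries
  for (b in c(100, 500)) {
    lo <- lr_at(b - 1e-6 * N, N, cfg)
    hi <- lr_at(b + 1e-6 * N, N, cfg)
    expect_lt(abs(hi - lo) / cfg$peak_lr, 1e-4)
  }
  # monotone up in warm-up, flat in hold, monotone down in decay
  lrs <- vapply(0:N, lr_at, 1, total_steps = N, cfg = cfg)
  expect_true(all(diff(lrs[1:101]) > 0))
  expect_true(all(abs(diff(lrs[102:500])) < 1e-18))
  expect_true(all(diff(lrs[502:1001]) < 0))
  expect_error(schedule_config(warmup_frac = 0.2), "sum")
})

test_that("early stopping fires when the minimum is over patience old", {
  expect_false(early_stop(c(5, 4, 3, 2, 1), 6))        # still improving
  expect_true(early_stop(c(1, rep(1.2, 7)), 6))        # 7 epochs stale
  expect_false(early_stop(c(1, rep(1.2, 6)), 6))       # exactly patience
  expect_false(early_stop(c(1.5, rep(1.6, 6), 1.4), 6))  # late improvement
  # ties do not count as improvement
  expect_true(early_stop(c(1, rep(1, 7)), 6))
  expect_false(early_stop(numeric(0), 6))
})

test_that("training reduces loss and is reproducible given a seed", {
  sc <- small_cohort()
  ex <- sc$cohort$examples
  y <- vapply(ex, function(e) e$label, 1L)
  # keep it tiny: 40 train patients, separable signal not required here
  m0 <- init_hier_model(tiny_hier_config(max_len = 256),
                        vocab_size(sc$cohort$vocab), seed = 1)
  r1 <- train_model(m0, ex[1:40], ex[41:60], epochs = 2, batch_size = 8,
                    peak_lr = 1e-3, seed = 9)
  expect_equal(nrow(r1$history), 2)
  expect_true(all(is.finite(r1$history$train_loss)))
  r2 <- train_model(m0, ex[1:40], ex[41:60], epochs = 2, batch_size = 8,
                    peak_lr = 1e-3, seed = 9)
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
  expect_equal(predict_risk(r1$model, ex[61:70]),
               predict_risk(r2$model, ex[61:70]), tolerance = 1e-12)
})

test_that("subgroup evaluation matches rates and reports three rows", {
  set.seed(5)
  n <- 400
  len <- c(sample(50:256, n / 2, TRUE), sample(257:500, n / 2, TRUE))
  y <- rbinom(n, 1, ifelse(len > 256, 0.3, 0.1))
  scores <- runif(n) + 0.3 * y
  ex <- lapply(seq_len(n), function(i)
    list(encoded = NULL, label = y[i], ehr_length = len[i],
         patient_id = i))
  rep <- subgroup_eval(ex, scores = scores, threshold = 256, n_boot = 5,
                       seed = 3)
  expect_equal(rep$subgroup, c("short", "long", "long_rate_matched"))
  expect_equal(rep$n[1] + rep$n[2], n)
  # matched positive rate within one positive count of the short rate
  rate_short <- rep$n_pos[1] / rep$n[1]
  k <- rep$n_pos[3]
  n_neg_long <- rep$n[3] - k
  expect_lt(abs(k / (k + n_neg_long) - rate_short), 1 / (k + n_neg_long))
  # identical subgroups give identical metrics
  short_ex <- ex[len <= 200][1:80]
  ex2 <- c(short_ex, lapply(short_ex, function(e) {
    e$ehr_length <- e$ehr_length + 300; e
  }))
  sc_short <- scores[len <= 200][1:80]
  sc2 <- c(sc_short, sc_short)
  rep2 <- subgroup_eval(ex2, scores = sc2, threshold = 256)
  expect_equal(rep2$auroc[1], rep2$auroc[2])
  # reproducible bootstrap
  rep3 <- subgroup_eval(ex, scores = scores, threshold = 256, n_boot = 5,
                        seed = 3)
  expect_equal(rep, rep3)
  # infeasible matching flagged when the long subgroup is rarer in cases
  y_flip <- rbinom(n, 1, ifelse(len > 256, 0.05, 0.4))
  ex_f <- lapply(seq_len(n), function(i)
    list(encoded = NULL, label = y_flip[i], ehr_length = len[i],
         patient_id = i))
  rep_f <- subgroup_eval(ex_f, scores = runif(n), threshold = 256)
  expect_true(is.na(rep_f$auroc[3]))
})

test_that("fraction curves use the full set at 1.0 and reproduce by seed", {
  sc <- small_cohort()
  ex <- sc$cohort$examples
  factory <- function(s) init_hier_model(tiny_hier_config(max_len = 256),
                                         vocab_size(sc$cohort$vocab),
                                         seed = s)
  tab <- fraction_curve(ex[1:50], ex[51:80], factory,
                        fractions = c(0.2, 1.0), n_seeds = 1, epochs = 1,
                        batch_size = 16, seed = 4)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_train[tab$fraction == 1], 50)
  expect_equal(tab$n_train[tab$fraction == 0.2], 10)
  tab2 <- fraction_curve(ex[1:50], ex[51:80], factory,
                         fractions = c(0.2, 1.0), n_seeds = 1, epochs = 1,
                         batch_size = 16, seed = 4)
  expect_equal(tab, tab2, tolerance = 1e-12)
})

test_that("modality ablation re-encodes per setting and adds one at a time", {
  sc <- small_cohort()
  g <- sc$gen
  bl <- data.frame(patient_id = g$truth$patient_id,
                   baseline_date = g$truth$baseline_date)
  vocab <- sc$cohort$vocab
  m <- init_hier_model(tiny_hier_config(max_len = 256), vocab_size(vocab),
                       seed = 2)
  tab <- modality_ablation(
    g$events, g$outcomes, "outcome", bl, vocab, model = m,
    eval_only = TRUE, base = c("diagnosis", "medication"),
    add_one_of = c("test", "smoking"), data_end = sc$params$data_end,
    max_len = 256)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$setting, c("base", "base+test", "base+smoking"))
  expect_true(all(is.finite(tab$auroc)))
  # adding a modality absent from the data leaves metrics unchanged
  ev2 <- g$events[g$events$modality != "bmi", ]
  tab2 <- modality_ablation(
    ev2, g$outcomes, "outcome", bl, vocab, model = m, eval_only = TRUE,
    base = c("diagnosis", "medication"), add_one_of = "bmi",
    data_end = sc$params$data_end, max_len = 256)
  expect_equal(tab2$auroc[1], tab2$auroc[2], tolerance = 1e-6)
  expect_equal(tab2$auprc[1], tab2$auprc[2], tolerance = 1e-6)
})
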