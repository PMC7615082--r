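# Supervised optimization: three-stage learning-rate schedule (linear
# warm-up, hold, cosine decay), Adam, early stopping on validation loss,
# best-weight restoration.

#' Three-stage learning-rate schedule configuration
#'
#' Defaults: 100 epochs split 10% linear warm-up / 40% hold at the peak /
#' 50% cosine decay to zero; batch size 128; early-stopping patience 6.
#' The peak learning rate is conventionally swept over {5e-5, 1e-4, 5e-4}
#' at full scale.
#'
#' @param total_epochs training epochs
#' @param warmup_frac,hold_frac,decay_frac stage fractions (must sum to 1)
#' @param peak_lr hold-stage learning rate
#' @param batch_size mini-batch size
#' @param patience early-stopping patience (epochs)
#' @return a `schedule_config` list
#' @export
schedule_config <- function(total_epochs = 100, warmup_frac = 0.10,
                            hold_frac = 0.40, decay_frac = 0.50,
                            peak_lr = 1e-4, batch_size = 128,
                            patience = 6) {
  if (abs(warmup_frac + hold_frac + decay_frac - 1) > 1e-9)
    stop("stage fractions must sum to 1")
  stopifnot(peak_lr > 0)
  structure(list(total_epochs = total_epochs, warmup_frac = warmup_frac,
                 hold_frac = hold_frac, decay_frac = decay_frac,
                 peak_lr = peak_lr, batch_size = batch_size,
                 patience = patience), class = "schedule_config")
}

#' Learning rate at a training step
#'
#' Linear 0 -> peak over the first 10% of steps, constant peak for the next
#' 40%, cosine peak -> 0 over the last 50%.  Continuous at both stage
#' boundaries; exactly `peak_lr` at the warm-up end and hold end, exactly 0
#' at the final step.
#'
#' @param step current step in `[0, total_steps]`
#' @param total_steps total steps of the run
#' @param cfg a [schedule_config()]
#' @return the learning rate
#' @export
lr_at <- function(step, total_steps, cfg = schedule_config()) {
  stopifnot(step >= 0, step <= total_steps)
  t <- step / total_steps
  w <- cfg$warmup_frac
  h <- cfg$warmup_frac + cfg$hold_frac
  if (t <= w) return(cfg$peak_lr * t / w)
  if (t <= h) return(cfg$peak_lr)
  cfg$peak_lr * 0.5 * (1 + cos(pi * (t - h) / (1 - h)))
}

#' Early-stopping decision
#'
#' Fires when the running-minimum validation loss is more than `patience`
#' epochs old (strict improvement counts; ties do not reset the counter).
#'
#' @param val_losses numeric vector of per-epoch validation losses so far
#' @param patience allowed epochs without improvement
#' @return logical
#' @export
early_stop <- function(val_losses, patience = 6) {
  if (!length(val_losses)) return(FALSE)
  length(val_losses) - which.min(val_losses) > patience
}

bce_loss <- function(labels, probs, pos_weight = 1, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  w <- ifelse(labels == 1, pos_weight, 1)
  -sum(w * (labels * log(p) + (1 - labels) * log(1 - p))) / sum(w)
}

# mini-batches grouped by sequence length (limits padding work); batch
# order shuffled per epoch
length_batches <- function(examples, batch_size) {
  ord <- order(vapply(examples, function(e) as.integer(e$encoded$true_length), 1L))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train a risk model with class-balanced resampled mini-batches
#'
#' Step-driven training: each mini-batch draws half positives (with
#' replacement) and half negatives, which keeps the gradient signal of a
#' low-prevalence outcome strong from the first step.  Learning rate
#' follows the three-stage schedule over `steps`.
#'
#' @param model a `hier_model` or `flat_model`
#' @param examples labelled cohort examples
#' @param steps number of optimization steps
#' @param batch_size examples per step (half positives, half negatives)
#' @param peak_lr hold-stage learning rate
#' @param seed integer seed (batch draws and dropout)
#' @param restart_check step at which a stalled run restarts from a
#'   jittered re-initialization (`0` disables)
#' @param restart_loss recent-training-loss threshold defining "stalled"
#' @param max_restarts restarts allowed before the run continues to the
#'   end regardless
#' @return the trained model
#' @export
train_balanced_steps <- function(model, examples, steps = 600,
                                 batch_size = 8, peak_lr = 1e-3,
                                 seed = 1L, restart_check = 200,
                                 restart_loss = 0.64, max_restarts = 2) {
  set.seed(seed)
  y <- vapply(examples, function(e) as.integer(e$label), 1L)
  pos <- which(y == 1)
  neg <- which(y == 0)
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  # long hold: the rare-feature transition happens at peak learning rate
  cfg <- schedule_config(warmup_frac = 0.1, hold_frac = 0.6,
                         decay_frac = 0.3, peak_lr = peak_lr,
                         batch_size = batch_size)
  init_model <- model
  opt <- adam_init(model$params)
  k <- max(1L, batch_size %/% 2L)
  restarts <- 0L
  recent <- numeric(0)
  s <- 0L
  while (s < steps) {
    s <- s + 1L
    idx <- c(sample(pos, k, replace = TRUE),
             sample(neg, k, replace = length(neg) < k))
    yb <- y[idx]
    fw <- model_fwd(model, examples[idx], train = TRUE)
    dlogit <- (fw$prob - yb) / length(idx)
    grads <- model_bwd(model, fw$cache, dlogit)
    st <- adam_step(model$params, grads, opt, lr_at(s, steps, cfg))
    model$params <- st$params
    opt <- st$state
    recent <- c(tail(recent, 49), bce_loss(yb, fw$prob))
    # stalled-run restart: rare-feature learning has an initialization-
    # dependent plateau; a run whose recent training loss still sits at
    # the balanced-chance level is abandoned for a jittered re-init (the
    # usual multi-start treatment of a non-convex fit)
    if (restart_check > 0 && s == restart_check &&
        restarts < max_restarts && mean(recent) > restart_loss) {
      restarts <- restarts + 1L
      model <- init_model
      model$params <- tree_map(function(x)
        x + stats::rnorm(length(x), sd = 0.002), init_model$params)
      opt <- adam_init(model$params)
      recent <- numeric(0)
      s <- 0L
    }
  }
  model
}

#' Train a risk model with Adam under the three-stage schedule
#'
#' Minimizes binary cross-entropy; evaluates validation loss each epoch,
#' stops early per [early_stop()], and restores the best-validation-loss
#' weights.
#'
#' @param model a `hier_model` or `flat_model`
#' @param train_examples,val_examples lists of cohort examples with labels
#' @param epochs training epochs
#' @param batch_size mini-batch size
#' @param peak_lr hold-stage learning rate
#' @param pos_weight loss weight on positive examples (`"balanced"` uses
#'   the inverse prevalence of the training labels; 1 = plain binary
#'   cross-entropy).  Class weighting counteracts the slow start of
#'   gradient training under low-prevalence outcomes
#' @param patience early-stopping patience; `Inf` disables
#' @param seed integer seed (batch order shuffling and dropout)
#' @param verbose print per-epoch losses
#' @return list(model, history): history is a data.frame (epoch,
#'   train_loss, val_loss)
#' @export
train_model <- function(model, train_examples, val_examples = NULL,
                        epochs = 3, batch_size = 32, peak_lr = 5e-4,
                        pos_weight = 1, patience = 6, seed = 1L,
                        verbose = FALSE) {
  set.seed(seed)
  all_y <- vapply(train_examples, function(e) as.integer(e$label), 1L)
  if (identical(pos_weight, "balanced"))
    pos_weight <- (1 - mean(all_y)) / max(mean(all_y), 1e-6)
  cfg <- schedule_config(total_epochs = epochs, peak_lr = peak_lr,
                         batch_size = batch_size, patience = patience)
  batches <- length_batches(train_examples, batch_size)
  total_steps <- epochs * length(batches)
  opt <- adam_init(model$params)
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(loss = Inf, params = model$params)
  val_losses <- numeric()

  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (bi in sample(length(batches))) {
      idx <- batches[[bi]]
      y <- all_y[idx]
      fw <- model_fwd(model, train_examples[idx], train = TRUE)
      step <- step + 1L
      w <- ifelse(y == 1, pos_weight, 1)
      dlogit <- w * (fw$prob - y) / sum(w)
      grads <- model_bwd(model, fw$cache, dlogit)
      st <- adam_step(model$params, grads, opt,
                      lr_at(step, total_steps, cfg))
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + bce_loss(y, fw$prob, pos_weight) * length(idx)
    }
    ep_loss <- ep_loss / length(train_examples)
    vl <- NA_real_
    if (!is.null(val_examples)) {
      vp <- predict_risk(model, val_examples, batch_size)
      vy <- vapply(val_examples, function(e) as.integer(e$label), 1L)
      vl <- bce_loss(vy, vp)
      val_losses <- c(val_losses, vl)
      if (vl < best$loss) best <- list(loss = vl, params = model$params)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", ep, ep_loss, vl))
    if (!is.null(val_examples) && early_stop(val_losses, patience)) break
  }
  if (!is.null(val_examples) && is.finite(best$loss))
    model$params <- best$params
  list(model = model, history = hist)
}
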