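# Adapted BYOL self-supervised pre-training for the hierarchical encoder.
#
# Online network: augmented input -> encoder -> (segment augmentation) ->
# aggregator -> per-segment projector -> predictor.  Target network: the
# *unaugmented* input through an EMA copy of encoder + projector, no
# gradients.  The loss is the summed per-augmented-timestep similarity
# 2 - 2*cos(online prediction, target projection), averaged over examples
# that have at least one augmented timestep.  One-sided, single-view: only
# the online path is augmented.  The random crop, which changes the segment
# grid, is shared by both paths so that timesteps stay aligned; token
# masking and segment augmentation remain online-only.

#' Augmentation configuration for pre-training
#'
#' @param p_crop probability of random-cropping the record sequence
#' @param p_mask per-token masking probability (token id -> `MASK`)
#' @param p_seg per-timestep probability of augmenting a latent segment
#'   representation
#' @param p_zero_given_aug probability an augmented segment is zeroed (the
#'   complement receives standard Gaussian noise)
#' @return an `augmentation_config` list
#' @export
augmentation_config <- function(p_crop = 0.5, p_mask = 0.2, p_seg = 0.5,
                                p_zero_given_aug = 0.85) {
  stopifnot(p_crop >= 0, p_crop <= 1, p_mask >= 0, p_mask <= 1,
            p_seg >= 0, p_seg <= 1,
            p_zero_given_aug >= 0, p_zero_given_aug <= 1)
  structure(list(p_crop = p_crop, p_mask = p_mask, p_seg = p_seg,
                 p_zero_given_aug = p_zero_given_aug,
                 p_noise_given_aug = 1 - p_zero_given_aug),
            class = "augmentation_config")
}

## ---- EHR-level augmentation ----------------------------------------------

# restrict an encoded sequence to visits v1..v2 (1-based visit index),
# shift to front, re-pad to the original length
crop_visits <- function(encoded, v1, v2) {
  n <- encoded$true_length
  visits <- encoded$position_ids[seq_len(n)]
  uv <- unique(visits)
  keep <- which(visits %in% uv[v1:v2])
  max_len <- length(encoded$token_ids)
  m <- length(keep)
  pad <- max_len - m
  pad_id <- RESERVED_TOKENS[["PAD"]]
  out <- encoded
  out$token_ids <- c(encoded$token_ids[keep], rep(pad_id, pad))
  out$age_ids <- c(encoded$age_ids[keep], rep(0L, pad))
  out$segment_ids <- c(encoded$segment_ids[keep], rep(0L, pad))
  out$position_ids <- c(encoded$position_ids[keep], rep(0L, pad))
  out$attention_mask <- c(rep(1L, m), rep(0L, pad))
  out$true_length <- m
  out
}

n_visits <- function(encoded) {
  length(unique(encoded$position_ids[seq_len(encoded$true_length)]))
}

# uniform over the V*(V+1)/2 contiguous visit intervals [v1, v2]
sample_crop_interval <- function(V) {
  v1 <- sample.int(V, 1, prob = V:1)
  v2 <- if (v1 < V) sample.int(V - v1 + 1L, 1) + v1 - 1L else V
  c(v1, v2)
}

# replace each real token id by MASK with probability p (age/segment/
# position ids kept)
mask_tokens <- function(encoded, p) {
  if (p <= 0) return(encoded)
  n <- encoded$true_length
  hit <- stats::runif(n) < p
  encoded$token_ids[seq_len(n)][hit] <- RESERVED_TOKENS[["MASK"]]
  encoded
}

#' EHR-level augmentation: random visit crop + random token masking
#'
#' With probability `p_crop` the sequence is replaced by a uniformly chosen
#' contiguous sub-interval of visits (at least one visit); each surviving
#' token id is then independently replaced by `MASK` with probability
#' `p_mask`.  Age, segment, and position ids are kept; the sequence is
#' re-padded to its original length.
#'
#' @param encoded an `encoded_sequence`
#' @param cfg an [augmentation_config()]
#' @return an augmented `encoded_sequence`
#' @export
augment_ehr <- function(encoded, cfg) {
  stopifnot(encoded$true_length >= 1)
  if (cfg$p_crop > 0 && stats::runif(1) < cfg$p_crop) {
    v <- sample_crop_interval(n_visits(encoded))
    encoded <- crop_visits(encoded, v[1], v[2])
  }
  mask_tokens(encoded, cfg$p_mask)
}

## ---- segment-level augmentation ------------------------------------------

#' Latent segment augmentation (online path only)
#'
#' Each masked-in segment independently joins the augmented set with
#' probability `p_seg`; members are zeroed with probability
#' `p_zero_given_aug` and otherwise receive additive standard Gaussian
#' noise.  Masked-out segments are never augmented.
#'
#' @param seg_reps matrix (n_segments x d) of segment representations
#' @param seg_mask 0/1 vector, one entry per row
#' @param cfg an [augmentation_config()]
#' @return list with `reps` (augmented matrix), `A` (logical: augmented
#'   rows), `zeroed` (logical), and `bwd` (gradient pass-through function)
#' @export
augment_segments <- function(seg_reps, seg_mask, cfg) {
  n <- nrow(seg_reps)
  A <- (stats::runif(n) < cfg$p_seg) & (seg_mask > 0)
  zeroed <- A & (stats::runif(n) < cfg$p_zero_given_aug)
  noised <- A & !zeroed
  reps <- seg_reps
  if (any(zeroed)) reps[zeroed, ] <- 0
  if (any(noised))
    reps[noised, ] <- reps[noised, , drop = FALSE] +
      matrix(stats::rnorm(sum(noised) * ncol(reps)), sum(noised))
  list(reps = reps, A = A, zeroed = zeroed,
       bwd = function(d) { d[zeroed, ] <- 0; d })
}

## ---- projector / predictor (per-timestep MLPs) ---------------------------

# One-hidden-layer MLP with batch normalization on the hidden layer
# (linear -> BN -> GELU -> linear), the BYOL head convention: the
# normalization keeps the similarity loss from collapsing onto a constant
# representation.  Xavier-scale init keeps output norms of the order of the
# input norms so the normalized loss has well-conditioned gradients.
init_mlp <- function(d_in, d_hidden, d_out) {
  list(fc1 = init_linear(d_in, d_hidden, 1 / sqrt(d_in)),
       bn = init_batchnorm(d_hidden),
       fc2 = init_linear(d_hidden, d_out, 1 / sqrt(d_hidden)))
}

mlp_fwd <- function(X, p) {
  A <- linear_fwd(X, p$fc1)
  bn <- batchnorm_fwd(A, p$bn)
  gl <- gelu_fwd(bn$Y)
  list(out = linear_fwd(gl$out, p$fc2), X = X, A = A, bn = bn,
       Bt = bn$Y, At = gl$t, G = gl$out)
}

mlp_bwd <- function(dOut, cache, p) {
  b2 <- linear_bwd(dOut, cache$G, p$fc2)
  dB <- gelu_bwd_cpp(cache$Bt, cache$At, b2$dX)
  bnb <- batchnorm_bwd(dB, cache$bn, p$bn)
  b1 <- linear_bwd(bnb$dX, cache$X, p$fc1)
  list(dX = b1$dX,
       grads = list(fc1 = b1$grads, bn = bnb$grads, fc2 = b2$grads))
}

## ---- similarity loss -----------------------------------------------------

#' Per-timestep BYOL similarity loss
#'
#' For each augmented timestep `t`, the loss is the squared distance of the
#' L2-normalized vectors, `2 - 2*cos(online_pred_t, target_proj_t)`, summed
#' over the augmented set.
#'
#' @param online_preds matrix (n_timesteps x p), online predictor outputs
#' @param target_projs matrix (n_timesteps x p), target projector outputs
#' @param A integer or logical index of augmented timesteps
#' @return scalar loss (>= 0)
#' @export
byol_loss <- function(online_preds, target_projs, A) {
  U <- online_preds[A, , drop = FALSE]
  V <- target_projs[A, , drop = FALSE]
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  if (any(nu == 0) || any(nv == 0)) stop("zero-norm representation")
  sum(2 - 2 * rowSums(U * V) / (nu * nv))
}

# loss + gradient w.r.t. the online rows; rows not in A get zero gradient
byol_loss_grad <- function(online_preds, target_projs, A, weight = 1) {
  U <- online_preds[A, , drop = FALSE]
  V <- target_projs[A, , drop = FALSE]
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  if (any(nu == 0) || any(nv == 0)) stop("zero-norm representation")
  Uh <- U / nu
  Vh <- V / nv
  cosv <- rowSums(Uh * Vh)
  dU <- -2 * (Vh - Uh * cosv) / nu
  G <- matrix(0, nrow(online_preds), ncol(online_preds))
  G[A, ] <- dU * weight
  list(loss = sum(2 - 2 * cosv), grad = G, cos = cosv)
}

## ---- BYOL state ----------------------------------------------------------

#' Initialize a BYOL pre-training state from a hierarchical model
#'
#' The online network holds encoder + projector + predictor; the target
#' network starts as a copy of encoder + projector and is thereafter updated
#' only by the exponential moving average.
#'
#' @param model a [init_hier_model()] model (its pooler/head are unused)
#' @param tau EMA decay factor
#' @param head_hidden hidden width of projector and predictor
#' @param proj_dim output dimension of projector/predictor
#' @param seed seed for head initialization
#' @return a `byol_state` list
#' @export
init_byol <- function(model, tau = 0.996, head_hidden = model$config$d,
                      proj_dim = model$config$d, seed = 1L) {
  set.seed(seed)
  enc <- model$params[c("emb", "extractor", "seg_pos", "cls", "aggregator")]
  projector <- init_mlp(model$config$d, head_hidden, proj_dim)
  predictor <- init_mlp(proj_dim, head_hidden, proj_dim)
  structure(list(config = model$config, vocab_size = model$vocab_size,
                 tau = tau,
                 online = list(enc = enc, proj = projector,
                               pred = predictor),
                 target = list(enc = enc, proj = projector)),
            class = "byol_state")
}

# hier_model view over an encoder parameter tree (heads absent)
enc_as_model <- function(state, enc) {
  structure(list(config = state$config, vocab_size = state$vocab_size,
                 params = enc), class = "hier_model")
}

#' Exponential-moving-average update of the target network
#'
#' Every target parameter becomes `tau * target + (1 - tau) * online`,
#' elementwise; online weights are untouched.
#'
#' @param state a [init_byol()] state
#' @return the state with updated target weights
#' @export
ema_update <- function(state) {
  blend <- function(t, o) {
    if (length(t) != length(o)) stop("target/online shape mismatch")
    state$tau * t + (1 - state$tau) * o
  }
  state$target$enc <- tree_map(blend, state$target$enc, state$online$enc)
  state$target$proj <- tree_map(blend, state$target$proj, state$online$proj)
  state
}

## ---- pre-training step and loop ------------------------------------------

#' One BYOL pre-training step
#'
#' Applies the shared random crop, the online-only token masking and segment
#' augmentation, computes the per-augmented-timestep similarity loss, takes
#' an SGD-momentum step on the online weights, and EMA-updates the target.
#'
#' @param batch list of cohort examples
#' @param state a [init_byol()] state
#' @param opt_state SGD-momentum state for the online weights, or `NULL`
#'   to create one
#' @param lr learning rate for this step
#' @param cfg an [augmentation_config()]
#' @param momentum SGD momentum
#' @return list(state, opt_state, loss, cos_aug): `cos_aug` is the mean
#'   cosine similarity at augmented timesteps
#' @export
pretrain_step <- function(batch, state, opt_state, lr,
                          cfg = augmentation_config(), momentum = 0.9) {
  # shared crop; token masking online-only
  cropped <- lapply(batch, function(e) {
    enc <- e$encoded
    if (cfg$p_crop > 0 && stats::runif(1) < cfg$p_crop) {
      v <- sample_crop_interval(n_visits(enc))
      enc <- crop_visits(enc, v[1], v[2])
    }
    enc
  })
  online_batch <- lapply(cropped, function(enc)
    list(encoded = mask_tokens(enc, cfg$p_mask)))
  target_batch <- lapply(cropped, function(enc) list(encoded = enc))

  online_model <- enc_as_model(state, state$online$enc)
  target_model <- enc_as_model(state, state$target$enc)

  aug_info <- NULL
  hook <- function(S0, seg_mask) {
    a <- augment_segments(S0, seg_mask, cfg)
    aug_info <<- a
    a
  }
  on_enc <- hier_encode_fwd(online_model, online_batch, train = TRUE,
                            seg_aug = hook)
  tg_enc <- hier_encode_fwd(target_model, target_batch, train = FALSE)

  proj_c <- mlp_fwd(on_enc$seg_states, state$online$proj)
  pred_c <- mlp_fwd(proj_c$out, state$online$pred)
  tg_proj <- mlp_fwd(tg_enc$seg_states, state$target$proj)$out

  A <- which(aug_info$A & on_enc$seg_mask > 0)
  B <- length(batch)
  nw <- on_enc$n_win
  ex_of <- rep(seq_len(B), each = nw)
  n_contrib <- length(unique(ex_of[A]))
  if (length(A) == 0 || n_contrib == 0)
    return(list(state = state, opt_state = opt_state, loss = 0,
                cos_aug = NA_real_))

  lg <- byol_loss_grad(pred_c$out, tg_proj, A, weight = 1 / n_contrib)
  loss <- lg$loss / n_contrib

  pred_b <- mlp_bwd(lg$grad, pred_c, state$online$pred)
  proj_b <- mlp_bwd(pred_b$dX, proj_c, state$online$proj)
  d_agg <- matrix(0, nrow(on_enc$agg_states), state$config$d)
  d_agg[-on_enc$cache$cls_rows, ] <- proj_b$dX
  enc_g <- hier_encode_bwd(online_model, on_enc, d_agg)

  grads <- list(enc = enc_g, proj = proj_b$grads, pred = pred_b$grads)
  online <- list(enc = state$online$enc, proj = state$online$proj,
                 pred = state$online$pred)
  if (is.null(opt_state)) opt_state <- sgd_momentum_init(online)
  stepped <- sgd_momentum_step(online, grads, opt_state, lr, momentum)
  state$online <- stepped$params
  state <- ema_update(state)
  list(state = state, opt_state = stepped$state, loss = loss,
       cos_aug = mean(lg$cos))
}

#' Run BYOL pre-training
#'
#' SGD with momentum 0.9 under a cosine-decay learning-rate schedule with a
#' 10% linear warm-up.
#'
#' @param examples list of cohort examples (labels unused)
#' @param state a [init_byol()] state
#' @param steps number of optimization steps
#' @param batch_size examples per step
#' @param lr peak learning rate
#' @param cfg an [augmentation_config()]
#' @param seed integer seed (batch sampling and augmentation draws)
#' @return list(state, log): `log` is a data.frame (step, loss, cos_aug)
#' @export
pretrain <- function(examples, state, steps = 200, batch_size = 32,
                     lr = 0.05, cfg = augmentation_config(), seed = 1L) {
  set.seed(seed)
  opt <- NULL
  log <- data.frame(step = integer(), loss = numeric(),
                    cos_aug = numeric())
  warm <- max(1, round(0.1 * steps))
  for (s in seq_len(steps)) {
    lr_s <- if (s <= warm) lr * s / warm else
      lr * 0.5 * (1 + cos(pi * (s - warm) / max(1, steps - warm)))
    idx <- sample.int(length(examples), min(batch_size, length(examples)))
    r <- pretrain_step(examples[idx], state, opt, lr_s, cfg)
    state <- r$state
    opt <- r$opt_state
    log <- rbind(log, data.frame(step = s, loss = r$loss,
                                 cos_aug = r$cos_aug))
  }
  list(state = state, log = log)
}

#' Turn a pre-trained BYOL state into a fine-tunable risk model
#'
#' The online encoder weights are kept; pooler and risk head are freshly
#' initialized.
#'
#' @param state a trained [init_byol()] state
#' @param seed seed for the fresh head weights
#' @return a `hier_model`
#' @export
byol_to_model <- function(state, seed = 1L) {
  set.seed(seed)
  d <- state$config$d
  params <- c(state$online$enc,
              list(pooler = init_linear(d, d), head = init_linear(d, 1)))
  structure(list(config = state$config, vocab_size = state$vocab_size,
                 params = params), class = "hier_model")
}
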