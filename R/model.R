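# The two-level hierarchical encoder and the flat truncating baseline.
#
# Hierarchical path: summed token/age/segment/position embeddings -> sliding
# window segmentation -> shared-weight transformer "local feature extractor"
# applied per window -> one representation per segment (first-position state,
# optionally mean) -> learned CLS vector prepended and segment-position
# embeddings added -> transformer "feature aggregator" -> tanh pooler on the
# CLS state -> sigmoid risk head.
#
# Flat path: CLS + (at most) the latest 256 records through a single
# transformer stack, first-timestep pooling, sigmoid head.
#
# All forward passes cache intermediates for the hand-written backward
# passes; attention runs in the compiled block kernel.

#' Hierarchical model configuration
#'
#' Defaults are the full-scale architecture: hidden size 150, 6 heads,
#' intermediate size 108, 4 extractor + 4 aggregator layers, window 50,
#' stride 30, maximum sequence length 1220, dropout 0.2, attention dropout
#' 0.3, GELU activations.
#'
#' @param d hidden size (divisible by `n_heads`)
#' @param n_heads attention heads
#' @param d_ff intermediate (feed-forward) size
#' @param extractor_layers,aggregator_layers transformer depth per level
#' @param window,stride sliding-window size and stride (records)
#' @param max_len maximum encoded sequence length
#' @param dropout,attn_dropout dropout rates (hidden / attention)
#' @param seg_pool `"first"` (first-position state) or `"mean"` over the
#'   window's real tokens
#' @return a `hier_config` list
#' @export
hier_config <- function(d = 150, n_heads = 6, d_ff = 108,
                        extractor_layers = 4, aggregator_layers = 4,
                        window = 50, stride = 30, max_len = 1220,
                        dropout = 0.2, attn_dropout = 0.3,
                        seg_pool = c("first", "mean")) {
  stopifnot(d %% n_heads == 0, window <= max_len, stride > 0,
            stride <= window)
  structure(list(type = "hier", d = d, n_heads = n_heads, d_ff = d_ff,
                 extractor_layers = extractor_layers,
                 aggregator_layers = aggregator_layers,
                 window = window, stride = stride, max_len = max_len,
                 dropout = dropout, attn_dropout = attn_dropout,
                 seg_pool = match.arg(seg_pool)), class = "hier_config")
}

#' Reduced hierarchical configuration for CPU-scale experiments
#' @param max_len maximum encoded sequence length
#' @return a `hier_config` list (d=48, 4 heads, 2+2 layers, no dropout)
#' @export
small_hier_config <- function(max_len = 512) {
  hier_config(d = 48, n_heads = 4, d_ff = 64, extractor_layers = 2,
              aggregator_layers = 2, window = 50, stride = 30,
              max_len = max_len, dropout = 0, attn_dropout = 0)
}

#' Flat (truncating) transformer configuration
#'
#' Defaults: hidden 150, 6 heads, intermediate 108, 8 layers, maximum
#' sequence length 256, dropout 0.2, attention dropout 0.3.
#' @param d,n_heads,d_ff,n_layers,max_len,dropout,attn_dropout see
#'   [hier_config()]
#' @return a `flat_config` list
#' @export
flat_config <- function(d = 150, n_heads = 6, d_ff = 108, n_layers = 8,
                        max_len = 256, dropout = 0.2, attn_dropout = 0.3) {
  stopifnot(d %% n_heads == 0)
  structure(list(type = "flat", d = d, n_heads = n_heads, d_ff = d_ff,
                 n_layers = n_layers, max_len = max_len, dropout = dropout,
                 attn_dropout = attn_dropout), class = "flat_config")
}

#' Reduced flat configuration matched to [small_hier_config()]
#' @return a `flat_config` list (d=48, 4 heads, 2 layers, no dropout)
#' @export
small_flat_config <- function() {
  flat_config(d = 48, n_heads = 4, d_ff = 64, n_layers = 2, max_len = 256,
              dropout = 0, attn_dropout = 0)
}

#' Sliding-window segmentation with guaranteed full coverage
#'
#' Windows start at 0, S, 2S, ...; when the last regular window would leave
#' trailing positions uncovered, one extra window anchored at `n - W` is
#' appended, so every position 0..n-1 lies in at least one window.  For
#' `n < W` a single window (right-padded downstream) is returned.
#'
#' @param n sequence length
#' @param W window size
#' @param S stride
#' @return integer matrix with columns `start`, `end` (0-based, end
#'   exclusive), one row per window, ordered by start
#' @export
segment_windows <- function(n, W, S) {
  stopifnot(n >= 1, W >= 1, S >= 1, S <= W)
  if (n <= W) {
    starts <- 0L
  } else {
    k <- floor((n - W) / S) + 1
    starts <- as.integer(S * (seq_len(k) - 1))
    if (starts[length(starts)] + W < n) starts <- c(starts, as.integer(n - W))
  }
  cbind(start = starts, end = starts + as.integer(W))
}

#' Attention footprint of a configuration
#'
#' The side of the largest attention score matrix any layer materializes,
#' and the per-layer score-matrix element counts.  For the hierarchical
#' model the side is `max(W, n_segments)`; for the flat model it is its
#' maximum sequence length.
#'
#' @param config a [hier_config()] or [flat_config()]
#' @return list with `side` and named `elements`
#' @export
attention_footprint <- function(config) {
  if (inherits(config, "hier_config")) {
    n_seg <- nrow(segment_windows(config$max_len, config$window,
                                  config$stride))
    list(side = max(config$window, n_seg),
         elements = c(extractor = n_seg * config$window^2,
                      aggregator = (n_seg + 1)^2))
  } else {
    list(side = config$max_len,
         elements = c(encoder = config$max_len^2))
  }
}

## ---- parameter initialization -------------------------------------------

N_AGES <- AGE_MAX + 1L  # ages 0..110, clamped

init_embeddings <- function(config, vocab_size, sd = 0.02) {
  d <- config$d
  list(tok = matrix(stats::rnorm(vocab_size * d, sd = sd), vocab_size, d),
       age = matrix(stats::rnorm(N_AGES * d, sd = sd), N_AGES, d),
       seg = matrix(stats::rnorm(2 * d, sd = sd), 2, d),
       pos = matrix(stats::rnorm(config$max_len * d, sd = sd),
                    config$max_len, d),
       ln = init_layernorm(d))
}

#' Initialize a hierarchical model
#' @param config a [hier_config()]
#' @param vocab_size vocabulary size (reserved ids included)
#' @param seed integer seed for weight initialization
#' @return a `hier_model` list with `config`, `vocab_size`, `params`
#' @export
init_hier_model <- function(config, vocab_size, seed = 1L) {
  set.seed(seed)
  d <- config$d
  n_seg_max <- nrow(segment_windows(config$max_len, config$window,
                                    config$stride))
  params <- list(
    emb = init_embeddings(config, vocab_size),
    extractor = lapply(seq_len(config$extractor_layers),
                       function(i) init_tf_layer(d, config$d_ff)),
    seg_pos = matrix(stats::rnorm((n_seg_max + 1) * d, sd = 0.02),
                     n_seg_max + 1, d),
    cls = stats::rnorm(d, sd = 0.02),
    aggregator = lapply(seq_len(config$aggregator_layers),
                        function(i) init_tf_layer(d, config$d_ff)),
    pooler = init_linear(d, d),
    head = init_linear(d, 1))
  structure(list(config = config, vocab_size = vocab_size, params = params),
            class = "hier_model")
}

#' Initialize a flat (truncating) model
#' @param config a [flat_config()]
#' @param vocab_size vocabulary size (reserved ids included)
#' @param seed integer seed for weight initialization
#' @return a `flat_model` list
#' @export
init_flat_model <- function(config, vocab_size, seed = 1L) {
  set.seed(seed)
  d <- config$d
  params <- list(
    emb = init_embeddings(config, vocab_size),
    layers = lapply(seq_len(config$n_layers),
                    function(i) init_tf_layer(d, config$d_ff)),
    pooler = init_linear(d, d),
    head = init_linear(d, 1))
  structure(list(config = config, vocab_size = vocab_size, params = params),
            class = "flat_model")
}

## ---- batch assembly ------------------------------------------------------

# stack encoded sequences (patient-major): ids length B*L each
stack_batch <- function(batch, L) {
  grab <- function(field, pad = 0L)
    unlist(lapply(batch, function(e) {
      v <- e$encoded[[field]][seq_len(min(L, length(e$encoded[[field]])))]
      c(v, rep(pad, L - length(v)))
    }), use.names = FALSE)
  list(tok = grab("token_ids", RESERVED_TOKENS[["PAD"]]),
       age = grab("age_ids"), seg = grab("segment_ids"),
       pos = grab("position_ids"), mask = as.numeric(grab("attention_mask")))
}

embed_fwd <- function(p, config, st, train = FALSE) {
  E <- p$emb$tok[st$tok, , drop = FALSE] +
    p$emb$age[st$age + 1L, , drop = FALSE] +
    p$emb$seg[st$seg + 1L, , drop = FALSE] +
    p$emb$pos[pmin(st$pos, config$max_len - 1L) + 1L, , drop = FALSE]
  ln <- layernorm_fwd(E, p$emb$ln)
  M <- if (train) dropout_mask(nrow(E), ncol(E), config$dropout) else NULL
  list(out = apply_mask(ln$Y, M), ln = ln, M = M, st = st)
}

embed_bwd <- function(dOut, cache, p, config, vocab_size) {
  dY <- apply_mask(dOut, cache$M)
  lnb <- layernorm_bwd(dY, cache$ln, p$emb$ln)
  dE <- lnb$dX
  st <- cache$st
  d <- ncol(dE)
  list(emb = list(
    tok = scatter_rows(vocab_size, st$tok, dE, d),
    age = scatter_rows(N_AGES, st$age + 1L, dE, d),
    seg = scatter_rows(2L, st$seg + 1L, dE, d),
    pos = scatter_rows(config$max_len,
                       pmin(st$pos, config$max_len - 1L) + 1L, dE, d),
    ln = lnb$grads))
}

## ---- hierarchical encoder forward/backward -------------------------------

#' Forward pass of the hierarchical encoder
#'
#' @param model a [init_hier_model()] model
#' @param batch list of cohort examples (each with `$encoded`)
#' @param train logical, enables dropout
#' @param seg_aug optional function `(seg_reps, seg_mask) -> list(reps,
#'   ...)` applied to segment representations before the aggregator (used by
#'   the self-supervised pre-training path); its extra fields are kept in
#'   the cache as `seg_aug_info`
#' @return list with `agg_states` (aggregator output, CLS rows included),
#'   `cls_states`, `seg_states`, `seg_mask`, `n_win`, and `cache`
#' @keywords internal
hier_encode_fwd <- function(model, batch, train = FALSE, seg_aug = NULL,
                            keep_cache = TRUE) {
  cf <- model$config
  p <- model$params
  B <- length(batch)
  W <- cf$window
  tl <- vapply(batch, function(e) as.integer(e$encoded$true_length), 1L)
  tlc <- pmin(pmax(tl, 1L), cf$max_len)
  L <- max(W, min(cf$max_len, max(tl)))
  st <- stack_batch(batch, L)
  em <- embed_fwd(p, cf, st, train)

  # per-patient window grids (so outputs do not depend on batch
  # composition); shorter patients are padded to the batch's window count
  # with dummy all-masked windows
  grids <- lapply(tlc, function(n) segment_windows(n, W, cf$stride))
  nw_b <- vapply(grids, nrow, 1L)
  nw <- max(nw_b)
  gidx <- integer(B * nw * W)
  km <- numeric(B * nw * W)
  off <- 0L
  for (b in seq_len(B)) {
    gi_b <- as.vector(t(grids[[b]][, "start"] +
                          matrix(rep(1:W, nw_b[b]), nw_b[b], W,
                                 byrow = TRUE)))
    n_dummy <- nw - nw_b[b]
    gi_full <- c(gi_b, rep(1:W, n_dummy)) + (b - 1L) * L
    sel <- off + seq_len(nw * W)
    gidx[sel] <- gi_full
    km[sel] <- c(st$mask[gi_b + (b - 1L) * L], numeric(n_dummy * W))
    off <- off + nw * W
  }
  Xw <- em$out[gidx, , drop = FALSE]

  ex <- tf_stack_fwd(Xw, p$extractor, W, cf$n_heads, km, train,
                     cf$dropout, cf$attn_dropout, keep_cache)

  idx0 <- seq(1L, by = W, length.out = B * nw)
  seg_mask <- km[idx0]
  if (cf$seg_pool == "first") {
    S0 <- ex$out[idx0, , drop = FALSE] * seg_mask
    pool_cache <- NULL
  } else {
    grp <- rep(seq_len(B * nw), each = W)
    cnt <- pmax(rowsum(km, grp)[, 1], 1)
    S0 <- (rowsum(ex$out * km, grp) / cnt) * seg_mask
    pool_cache <- list(grp = grp, cnt = cnt)
  }

  aug <- if (is.null(seg_aug)) NULL else seg_aug(S0, seg_mask)
  S1 <- if (is.null(aug)) S0 else aug$reps

  # aggregator input: CLS + segments, with segment-position embeddings
  Lb <- nw + 1L
  cls_rows <- seq(1L, by = Lb, length.out = B)
  A <- matrix(0, B * Lb, cf$d)
  A[cls_rows, ] <- matrix(p$cls, B, cf$d, byrow = TRUE)
  A[-cls_rows, ] <- S1
  pos_idx <- rep(seq_len(Lb), B)   # CLS takes segment-position 1
  A <- A + p$seg_pos[pos_idx, , drop = FALSE]
  akm <- numeric(B * Lb)
  akm[cls_rows] <- 1
  akm[-cls_rows] <- seg_mask
  Magg <- if (train) dropout_mask(nrow(A), ncol(A), cf$dropout) else NULL
  ag <- tf_stack_fwd(apply_mask(A, Magg), p$aggregator, Lb, cf$n_heads, akm,
                     train, cf$dropout, cf$attn_dropout, keep_cache)

  list(agg_states = ag$out,
       cls_states = ag$out[cls_rows, , drop = FALSE],
       seg_states = ag$out[-cls_rows, , drop = FALSE],
       seg_mask = seg_mask, n_win = nw,
       cache = if (keep_cache)
         list(em = em, gidx = gidx, km = km, ex = ex, idx0 = idx0,
              pool_cache = pool_cache, seg_mask = seg_mask,
              seg_aug_info = aug, cls_rows = cls_rows,
              pos_idx = pos_idx, Magg = Magg, ag = ag, L = L,
              B = B, nw = nw)
       else list(cls_rows = cls_rows))
}

#' Backward pass of the hierarchical encoder
#'
#' @param model the model
#' @param enc the [hier_encode_fwd()] result
#' @param d_agg gradient w.r.t. `agg_states` (same shape)
#' @return gradient tree for `model$params` (heads excluded)
#' @keywords internal
hier_encode_bwd <- function(model, enc, d_agg) {
  cf <- model$config
  p <- model$params
  ca <- enc$cache
  agb <- tf_stack_bwd(d_agg, ca$ag$caches, p$aggregator)
  dA <- apply_mask(agb$dX, ca$Magg)
  g_seg_pos <- scatter_rows(nrow(p$seg_pos), ca$pos_idx, dA, cf$d)
  g_cls <- colSums(dA[ca$cls_rows, , drop = FALSE])
  dS1 <- dA[-ca$cls_rows, , drop = FALSE]

  aug <- ca$seg_aug_info
  dS0 <- if (is.null(aug)) dS1 else aug$bwd(dS1)
  dS0 <- dS0 * ca$seg_mask

  W <- cf$window
  dXw <- matrix(0, length(ca$km), cf$d)
  if (cf$seg_pool == "first") {
    dXw[ca$idx0, ] <- dS0
  } else {
    pc <- ca$pool_cache
    dXw <- (dS0 / pc$cnt)[pc$grp, , drop = FALSE] * ca$km
  }
  exb <- tf_stack_bwd(dXw, ca$ex$caches, p$extractor)

  dE <- scatter_rows(ca$B * ca$L, ca$gidx, exb$dX, cf$d)
  g_emb <- embed_bwd(dE, ca$em, p, cf, model$vocab_size)

  list(emb = g_emb$emb, extractor = exb$grads, seg_pos = g_seg_pos,
       cls = g_cls, aggregator = agb$grads)
}

## ---- risk head -----------------------------------------------------------

risk_head_fwd <- function(p, cls_states) {
  pre <- linear_fwd(cls_states, p$pooler)
  pooled <- tanh(pre)
  logit <- linear_fwd(pooled, p$head)[, 1]
  list(prob = stats::plogis(logit), logit = logit, pooled = pooled,
       cls_states = cls_states)
}

risk_head_bwd <- function(p, head_cache, dlogit) {
  hb <- linear_bwd(matrix(dlogit, ncol = 1), head_cache$pooled, p$head)
  dpre <- hb$dX * (1 - head_cache$pooled^2)
  pb <- linear_bwd(dpre, head_cache$cls_states, p$pooler)
  list(d_cls = pb$dX, grads = list(pooler = pb$grads, head = hb$grads))
}

## ---- full supervised forward/backward ------------------------------------

#' Supervised forward pass (risk probabilities)
#' @param model a `hier_model` or `flat_model`
#' @param batch list of cohort examples
#' @param train logical
#' @return list(prob, cache)
#' @keywords internal
model_fwd <- function(model, batch, train = FALSE, keep_cache = TRUE) {
  if (inherits(model, "hier_model")) {
    enc <- hier_encode_fwd(model, batch, train, keep_cache = keep_cache)
    hd <- risk_head_fwd(model$params, enc$cls_states)
    list(prob = hd$prob, cache = list(enc = enc, hd = hd))
  } else {
    flat_fwd(model, batch, train, keep_cache = keep_cache)
  }
}

# gradient of mean binary cross-entropy w.r.t. logits is (p - y)/B
model_bwd <- function(model, cache, dlogit) {
  if (inherits(model, "hier_model")) {
    hb <- risk_head_bwd(model$params, cache$hd, dlogit)
    d_agg <- matrix(0, nrow(cache$enc$agg_states), model$config$d)
    d_agg[cache$enc$cache$cls_rows, ] <- hb$d_cls
    g <- hier_encode_bwd(model, cache$enc, d_agg)
    c(g, hb$grads)
  } else {
    flat_bwd(model, cache, dlogit)
  }
}

## ---- flat baseline -------------------------------------------------------

flat_fwd <- function(model, batch, train = FALSE, keep_cache = TRUE) {
  cf <- model$config
  p <- model$params
  B <- length(batch)
  tl <- vapply(batch, function(e) as.integer(e$encoded$true_length), 1L)
  k <- pmin(tl, cf$max_len)
  Lk <- max(k)
  Lb <- Lk + 1L  # CLS first

  # latest-k records per patient, oldest -> newest, right-padded
  pad_id <- RESERVED_TOKENS[["PAD"]]
  cls_id <- RESERVED_TOKENS[["CLS"]]
  take <- function(e, ki) {
    i <- seq.int(e$encoded$true_length - ki + 1L, e$encoded$true_length)
    list(tok = e$encoded$token_ids[i], age = e$encoded$age_ids[i],
         seg = e$encoded$segment_ids[i], pos = e$encoded$position_ids[i])
  }
  tok <- age <- seg <- pos <- integer(B * Lb)
  mask <- numeric(B * Lb)
  for (b in seq_len(B)) {
    tt <- take(batch[[b]], k[b])
    o <- (b - 1L) * Lb
    tok[o + 1L] <- cls_id
    age[o + 1L] <- tt$age[1]
    seg[o + 1L] <- 0L
    pos[o + 1L] <- 0L
    j <- seq_len(k[b])
    tok[o + 1L + j] <- tt$tok
    age[o + 1L + j] <- tt$age
    seg[o + 1L + j] <- tt$seg
    pos[o + 1L + j] <- tt$pos
    if (k[b] < Lk) tok[o + 1L + seq.int(k[b] + 1L, Lk)] <- pad_id
    mask[o + seq_len(k[b] + 1L)] <- 1
  }
  st <- list(tok = tok, age = age, seg = seg, pos = pos, mask = mask)
  em <- embed_fwd(p, cf, st, train)
  tf <- tf_stack_fwd(em$out, p$layers, Lb, cf$n_heads, mask, train,
                     cf$dropout, cf$attn_dropout, keep_cache)
  cls_rows <- seq(1L, by = Lb, length.out = B)
  hd <- risk_head_fwd(p, tf$out[cls_rows, , drop = FALSE])
  list(prob = hd$prob,
       cache = if (keep_cache)
         list(em = em, tf = tf, hd = hd, cls_rows = cls_rows,
              Lb = Lb, B = B))
}

flat_bwd <- function(model, cache, dlogit) {
  cf <- model$config
  p <- model$params
  hb <- risk_head_bwd(p, cache$hd, dlogit)
  dOut <- matrix(0, cache$B * cache$Lb, cf$d)
  dOut[cache$cls_rows, ] <- hb$d_cls
  tfb <- tf_stack_bwd(dOut, cache$tf$caches, p$layers)
  g_emb <- embed_bwd(tfb$dX, cache$em, p, cf, model$vocab_size)
  c(list(emb = g_emb$emb, layers = tfb$grads), hb$grads)
}

## ---- prediction ----------------------------------------------------------

#' Predict risk probabilities for a set of examples
#' @param model a `hier_model` or `flat_model`
#' @param examples list of cohort examples
#' @param batch_size mini-batch size for the forward passes
#' @return numeric vector of probabilities in (0,1), one per example
#' @export
predict_risk <- function(model, examples, batch_size = 64) {
  n <- length(examples)
  # group by similar length to limit padding work
  ord <- order(vapply(examples, function(e) as.integer(e$encoded$true_length), 1L))
  probs <- numeric(n)
  for (i in seq(1, n, by = batch_size)) {
    sel <- ord[i:min(i + batch_size - 1, n)]
    probs[sel] <- model_fwd(model, examples[sel], train = FALSE,
                            keep_cache = FALSE)$prob
  }
  probs
}

#' Save / load a model checkpoint (config embedded)
#' @param model model object
#' @param path file path
#' @export
save_checkpoint <- function(model, path) saveRDS(model, path)

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
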