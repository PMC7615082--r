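# Minimal neural-network core: parameter trees, layers with explicit
# forward/backward passes, and optimizers.  Parameters live in nested named
# lists whose leaves are numeric matrices/vectors; gradients mirror the tree.

#' @useDynLib hierehr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- parameter-tree utilities -------------------------------------------

is_param_leaf <- function(x) is.numeric(x)

#' Apply a function to every leaf of one or two parameter trees
#' @param f function of one (or two) leaves
#' @param a,b parameter trees with identical structure (`b` optional)
#' @return a tree with the same structure
#' @keywords internal
tree_map <- function(f, a, b = NULL) {
  if (is_param_leaf(a)) {
    if (is.null(b)) f(a) else f(a, b)
  } else {
    out <- lapply(seq_along(a), function(i) {
      tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    })
    names(out) <- names(a)
    out
  }
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)

#' Sum of a tree of gradients into another (a + s*b), elementwise
#' @keywords internal
tree_axpy <- function(a, b, s = 1) tree_map(function(x, y) x + s * y, a, b)

## ---- primitive layers ----------------------------------------------------

init_linear <- function(d_in, d_out, sd = 0.02) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(X, p) add_bias_inplace(X %*% p$W, p$b)

linear_bwd <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

layernorm_fwd <- function(X, p, eps = 1e-12) {
  layernorm_fwd_cpp(X, p$g, p$b, eps)
}

layernorm_bwd <- function(dY, cache, p) {
  r <- layernorm_bwd_cpp(dY, cache$xhat, cache$istd, p$g)
  list(dX = r$dX, grads = list(g = r$dg, b = r$db))
}

# GELU, tanh approximation (BERT convention); forward caches the tanh term
# so the backward pass reuses it (compiled single-pass kernels)
gelu_fwd <- function(x) gelu_fwd_cpp(x)
gelu <- function(x) gelu_fwd_cpp(x)$out

# inverted dropout mask (already scaled by 1/(1-p)); NULL when p == 0 or eval
dropout_mask <- function(n_row, n_col, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n_row * n_col) >= p) / (1 - p), n_row, n_col)
}

apply_mask <- function(X, M) if (is.null(M)) X else X * M

## ---- batch normalization (projector/predictor hidden layers) -------------

init_batchnorm <- function(d) list(g = rep(1, d), b = numeric(d))

# column-wise (feature) normalization over the batch; train mode only --
# the heads that use it exist only during pre-training
batchnorm_fwd <- function(X, p, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = nrow(X))
  v <- colMeans(Xc * Xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- Xc * rep(istd, each = nrow(X))
  list(Y = xhat * rep(p$g, each = nrow(X)) + rep(p$b, each = nrow(X)),
       xhat = xhat, istd = istd)
}

batchnorm_bwd <- function(dY, cache, p) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(p$g, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- rep(cache$istd, each = n) *
    (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n))
  list(dX = dX, grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

## ---- transformer encoder layer (post-LN, BERT style) ---------------------

init_tf_layer <- function(d, d_ff, sd = 0.02) {
  list(q = init_linear(d, d, sd), k = init_linear(d, d, sd),
       v = init_linear(d, d, sd), o = init_linear(d, d, sd),
       ln1 = init_layernorm(d),
       ff1 = init_linear(d, d_ff, sd), ff2 = init_linear(d_ff, d, sd),
       ln2 = init_layernorm(d))
}

#' One transformer encoder layer over stacked equal-length blocks
#'
#' @param X activations, (n_blocks*block_len) x d
#' @param p layer parameters
#' @param block_len tokens per attention block
#' @param n_heads number of attention heads
#' @param key_mask 0/1 vector, one entry per row of `X`
#' @param train logical; enables dropout
#' @param dropout,attn_dropout dropout rates (hidden / attention probs)
#' @param keep_cache retain intermediates for a backward pass (disable for
#'   inference to keep memory flat)
#' @return list(out, cache)
#' @keywords internal
tf_layer_fwd <- function(X, p, block_len, n_heads, key_mask,
                         train = FALSE, dropout = 0, attn_dropout = 0,
                         keep_cache = TRUE) {
  Q <- linear_fwd(X, p$q); K <- linear_fwd(X, p$k); V <- linear_fwd(X, p$v)
  Mattn <- if (train && attn_dropout > 0)
    dropout_mask(block_len * n_heads, nrow(X), attn_dropout) else NULL
  at <- mha_forward_cpp(Q, K, V, block_len, n_heads, key_mask,
                        if (is.null(Mattn)) NULL else Mattn)$ctx
  O <- linear_fwd(at, p$o)
  M1 <- if (train) dropout_mask(nrow(X), ncol(X), dropout) else NULL
  ln1 <- layernorm_fwd(X + apply_mask(O, M1), p$ln1)
  H1 <- ln1$Y
  A <- linear_fwd(H1, p$ff1)
  gl <- gelu_fwd(A)
  G <- gl$out
  FF <- linear_fwd(G, p$ff2)
  M2 <- if (train) dropout_mask(nrow(X), ncol(X), dropout) else NULL
  ln2 <- layernorm_fwd(H1 + apply_mask(FF, M2), p$ln2)
  if (!keep_cache) return(list(out = ln2$Y, cache = NULL))
  list(out = ln2$Y,
       cache = list(X = X, Q = Q, K = K, V = V,
                    ctx = at, Mattn = Mattn, M1 = M1, ln1 = ln1,
                    H1 = H1, A = A, At = gl$t, G = G, M2 = M2, ln2 = ln2,
                    block_len = block_len, n_heads = n_heads,
                    key_mask = key_mask))
}

tf_layer_bwd <- function(dOut, cache, p) {
  ln2b <- layernorm_bwd(dOut, cache$ln2, p$ln2)
  dR2 <- ln2b$dX
  dFF <- apply_mask(dR2, cache$M2)
  ff2b <- linear_bwd(dFF, cache$G, p$ff2)
  dA <- gelu_bwd_cpp(cache$A, cache$At, ff2b$dX)
  ff1b <- linear_bwd(dA, cache$H1, p$ff1)
  dH1 <- dR2 + ff1b$dX
  ln1b <- layernorm_bwd(dH1, cache$ln1, p$ln1)
  dR1 <- ln1b$dX
  dO <- apply_mask(dR1, cache$M1)
  ob <- linear_bwd(dO, cache$ctx, p$o)
  atb <- mha_backward_cpp(ob$dX, cache$Q, cache$K, cache$V,
                          cache$block_len, cache$n_heads, cache$key_mask,
                          if (is.null(cache$Mattn)) NULL else cache$Mattn)
  qb <- linear_bwd(atb$dQ, cache$X, p$q)
  kb <- linear_bwd(atb$dK, cache$X, p$k)
  vb <- linear_bwd(atb$dV, cache$X, p$v)
  dX <- dR1 + qb$dX + kb$dX + vb$dX
  list(dX = dX,
       grads = list(q = qb$grads, k = kb$grads, v = vb$grads, o = ob$grads,
                    ln1 = ln1b$grads, ff1 = ff1b$grads, ff2 = ff2b$grads,
                    ln2 = ln2b$grads))
}

# Stack of layers sharing block structure
tf_stack_fwd <- function(X, layers, block_len, n_heads, key_mask,
                         train = FALSE, dropout = 0, attn_dropout = 0,
                         keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- tf_layer_fwd(X, layers[[i]], block_len, n_heads, key_mask,
                      train, dropout, attn_dropout, keep_cache)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

tf_stack_bwd <- function(dOut, caches, layers) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- tf_layer_bwd(dOut, caches[[i]], layers[[i]])
    dOut <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dOut, grads = grads)
}

## ---- embedding scatter ---------------------------------------------------

# accumulate rows of dE into a zero table of `n_rows` rows, grouped by ids
scatter_rows <- function(n_rows, ids, dE, d) {
  out <- matrix(0, n_rows, d)
  r <- rowsum(dE, group = ids)
  out[as.integer(rownames(r)), ] <- r
  out
}

## ---- optimizers ----------------------------------------------------------

#' Adam optimizer state for a parameter tree
#' @keywords internal
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  list(params = tree_map(function(p, u) p - u, params, upd), state = state)
}

sgd_momentum_init <- function(params) list(v = tree_zeros_like(params))

sgd_momentum_step <- function(params, grads, state, lr, momentum = 0.9) {
  state$v <- tree_map(function(v, g) momentum * v + g, state$v, grads)
  list(params = tree_map(function(p, v) p - lr * v, params, state$v),
       state = state)
}
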