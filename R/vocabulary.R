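# Token vocabulary with reserved ids.  Ids are 1-based (R convention):
# PAD = 1, UNK = 2, MASK = 3, CLS = 4; data tokens start at 5.

RESERVED_TOKENS <- c(PAD = 1L, UNK = 2L, MASK = 3L, CLS = 4L)

#' Build a vocabulary from a set of tokens
#'
#' @param tokens character vector of data tokens (duplicates collapsed,
#'   sorted for determinism)
#' @return a `vocabulary` object: bijection token <-> integer id with the
#'   four reserved ids (`PAD`, `UNK`, `MASK`, `CLS`) prepended
#' @export
build_vocab <- function(tokens) {
  tokens <- sort(unique(as.character(tokens)))
  if (any(tokens %in% names(RESERVED_TOKENS)))
    stop("data tokens may not collide with reserved tokens")
  ids <- seq_along(tokens) + length(RESERVED_TOKENS)
  tab <- c(RESERVED_TOKENS, stats::setNames(as.integer(ids), tokens))
  structure(list(id_of = tab, token_of = names(tab)), class = "vocabulary")
}

#' Vocabulary size (reserved ids included)
#' @param vocab a [build_vocab()] object
#' @export
vocab_size <- function(vocab) length(vocab$id_of)

#' Map tokens to integer ids (`UNK` for unseen tokens)
#' @param vocab a [build_vocab()] object
#' @param tokens character vector
#' @return integer vector of ids
#' @export
vocab_encode <- function(vocab, tokens) {
  ids <- unname(vocab$id_of[tokens])
  ids[is.na(ids)] <- RESERVED_TOKENS[["UNK"]]
  as.integer(ids)
}

#' Map integer ids back to tokens
#' @param vocab a [build_vocab()] object
#' @param ids integer vector of ids
#' @return character vector of tokens
#' @export
vocab_decode <- function(vocab, ids) vocab$token_of[ids]
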