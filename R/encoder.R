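# Wordpiece tokenization and a tiny trainable transformer encoder.
#
# The encoder follows the standard pre-norm transformer layout (token +
# position embeddings, single-head scaled dot-product self-attention, a
# position-wise feed-forward block, residual connections, layer norm) but is
# deliberately small: it is meant to be trained from scratch on desk-scale
# corpora, and every experiment here runs on CPU. Hidden size, depth and
# maximum length are free parameters; nothing in the fusion machinery depends
# on them beyond the hidden size d_T.

PAD <- "[PAD]"; UNK <- "[UNK]"; CLS <- "[CLS]"; SEP_TOK <- "[SEP]"

#' Build a wordpiece vocabulary from reference text
#'
#' The vocabulary contains the special tokens, every distinct lowercased word
#' of the reference texts, and full single-character coverage (initial and
#' `##`-continuation pieces), so any unseen word decomposes into character
#' pieces rather than collapsing to `[UNK]`.
#'
#' @param texts Character vector of reference text.
#' @param extra_words Additional surface forms to include whole.
#' @return Character vector of pieces, specials first.
#' @export
wordpiece_vocab <- function(texts, extra_words = character(0)) {
  words <- tolower(unlist(strsplit(texts, "\\s+")))
  words <- unique(c(words[nzchar(words)], tolower(extra_words)))
  chars <- unique(unlist(strsplit(c(words, letters, as.character(0:9)), "")))
  sort_unique <- function(x) sort(unique(x), method = "radix")
  c(PAD, UNK, CLS, SEP_TOK,
    sort_unique(c(chars, paste0("##", chars), words)))
}

vocab_env <- function(vocab) {
  e <- new.env(parent = emptyenv(), size = length(vocab))
  for (i in seq_along(vocab)) assign(vocab[i], i, envir = e)
  e
}

# Greedy longest-match wordpiece split of one lowercased word.
split_word <- function(word, venv) {
  n <- nchar(word)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (l in seq(n - i + 1L, 1L)) {
      cand <- substr(word, i, i + l - 1L)
      if (i > 1L) cand <- paste0("##", cand)
      if (exists(cand, envir = venv, inherits = FALSE)) { hit <- cand; break }
    }
    if (is.null(hit)) return(UNK)
    out <- c(out, hit)
    i <- i + l
  }
  out
}

#' Encode a word sequence onto the wordpiece grid
#'
#' Produces the encoder-ready representation of one sentence: the wordpiece
#' sequence (with `[CLS]`/`[SEP]` and optional `[PAD]` up to `pad_to`), the
#' integer piece ids, the word-to-piece index ranges, and the attention mask.
#' Special and padding positions belong to no word.
#'
#' @param tokenizer A list with elements `vocab` and `venv` as produced by
#'   [new_tiny_encoder()] (the encoder doubles as its tokenizer) or
#'   `list(vocab = v, venv = kgfuse:::vocab_env(v))`.
#' @param words Character vector of word tokens.
#' @param pad_to Optional total length to pad to.
#' @param max_len Maximum piece length; longer inputs are truncated with a
#'   warning. Defaults to the tokenizer's own `max_len` when it has one.
#' @return An object of class `encoded_input` with fields `wordpieces`,
#'   `piece_ids`, `word_to_pieces` (list of `c(first, last)` 1-based piece
#'   ranges per word) and `attention_mask`.
#' @export
encode_words <- function(tokenizer, words, pad_to = NULL, max_len = NULL) {
  if (is.null(max_len)) {
    max_len <- if (!is.null(tokenizer$max_len)) tokenizer$max_len else 512L
  }
  venv <- tokenizer$venv
  pieces <- CLS
  w2p <- vector("list", length(words))
  for (k in seq_along(words)) {
    wp <- split_word(tolower(words[k]), venv)
    w2p[[k]] <- c(length(pieces) + 1L, length(pieces) + length(wp))
    pieces <- c(pieces, wp)
  }
  pieces <- c(pieces, SEP_TOK)
  if (length(pieces) > max_len) {
    warning("sequence of ", length(pieces),
            " wordpieces truncated to max_len = ", max_len)
    pieces <- c(pieces[seq_len(max_len - 1L)], SEP_TOK)
    # Words falling beyond the truncation point keep a NULL range so the
    # word -> piece list stays aligned with the word sequence.
    w2p <- lapply(w2p, function(r) {
      if (r[1] >= max_len) NULL else c(r[1], min(r[2], max_len - 1L))
    })
  }
  mask <- rep(1L, length(pieces))
  if (!is.null(pad_to) && pad_to > length(pieces)) {
    mask <- c(mask, rep(0L, pad_to - length(pieces)))
    pieces <- c(pieces, rep(PAD, pad_to - length(pieces)))
  }
  ids <- vapply(pieces, function(p) {
    if (exists(p, envir = venv, inherits = FALSE)) get(p, envir = venv)
    else get(UNK, envir = venv)
  }, integer(1), USE.NAMES = FALSE)
  structure(list(wordpieces = pieces, piece_ids = ids,
                 word_to_pieces = w2p, attention_mask = mask),
            class = "encoded_input")
}

encoder_param_names <- function(n_layers) {
  per <- function(l) paste0("L", l, "_",
                            c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo",
                              "ln2_g", "ln2_b", "W1", "b1", "W2", "b2"))
  c("tok_emb", "pos_emb", unlist(lapply(seq_len(n_layers), per)),
    "lnf_g", "lnf_b")
}

#' Create a tiny transformer text encoder
#'
#' Randomly initialized, trained (if at all) by the caller; deterministic for
#' a fixed seed. The returned object also carries its wordpiece tokenizer.
#'
#' @param vocab Wordpiece vocabulary (see [wordpiece_vocab()]).
#' @param hidden Hidden size d_T.
#' @param n_layers Number of transformer blocks.
#' @param max_len Maximum sequence length in wordpieces.
#' @param seed Integer seed for the parameter initialization.
#' @return Object of class `tiny_encoder`: list with `vocab`, `venv`,
#'   `hidden`, `n_layers`, `max_len`, `seed` and `params`.
#' @export
new_tiny_encoder <- function(vocab, hidden = 32L, n_layers = 2L,
                             max_len = 128L, seed = 1L) {
  set.seed(seed)
  d <- hidden
  params <- list(tok_emb = rmat(length(vocab), d, 0.05),
                 pos_emb = rmat(max_len, d, 0.05))
  for (l in seq_len(n_layers)) {
    params[[paste0("L", l, "_ln1_g")]] <- matrix(1, 1L, d)
    params[[paste0("L", l, "_ln1_b")]] <- matrix(0, 1L, d)
    params[[paste0("L", l, "_Wq")]] <- rmat(d, d, 1 / sqrt(d))
    params[[paste0("L", l, "_Wk")]] <- rmat(d, d, 1 / sqrt(d))
    params[[paste0("L", l, "_Wv")]] <- rmat(d, d, 1 / sqrt(d))
    params[[paste0("L", l, "_Wo")]] <- rmat(d, d, 1 / sqrt(d))
    params[[paste0("L", l, "_ln2_g")]] <- matrix(1, 1L, d)
    params[[paste0("L", l, "_ln2_b")]] <- matrix(0, 1L, d)
    params[[paste0("L", l, "_W1")]] <- rmat(d, 2L * d, 1 / sqrt(d))
    params[[paste0("L", l, "_b1")]] <- matrix(0, 1L, 2L * d)
    params[[paste0("L", l, "_W2")]] <- rmat(2L * d, d, 1 / sqrt(2 * d))
    params[[paste0("L", l, "_b2")]] <- matrix(0, 1L, d)
  }
  params$lnf_g <- matrix(1, 1L, d)
  params$lnf_b <- matrix(0, 1L, d)
  structure(list(vocab = vocab, venv = vocab_env(vocab), hidden = d,
                 n_layers = n_layers, max_len = max_len, seed = seed,
                 params = params),
            class = "tiny_encoder")
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat(sprintf("tiny_encoder: hidden %d, %d layers, vocab %d, max_len %d\n",
              x$hidden, x$n_layers, length(x$vocab), x$max_len))
  invisible(x)
}

# Forward pass on a tape. pnodes is a named list of ad leaves matching the
# encoder parameter names; piece_ids integer vector; mask NULL or 0/1 vector
# (padding positions masked out of attention).
encoder_forward <- function(tape, enc, pnodes, piece_ids, mask = NULL,
                            dropout = 0) {
  L <- length(piece_ids)
  X <- ad_add(ad_rows(pnodes$tok_emb, piece_ids),
              ad_rows(pnodes$pos_emb, seq_len(L)))
  attn_mask <- NULL
  if (!is.null(mask) && any(mask == 0L)) {
    attn_mask <- matrix(rep(ifelse(mask == 0L, -1e9, 0), each = L), L, L)
  }
  scale <- 1 / sqrt(enc$hidden)
  for (l in seq_len(enc$n_layers)) {
    p <- function(nm) pnodes[[paste0("L", l, "_", nm)]]
    H <- ad_layernorm(X, p("ln1_g"), p("ln1_b"))
    Q <- ad_matmul(H, p("Wq")); K <- ad_matmul(H, p("Wk"))
    V <- ad_matmul(H, p("Wv"))
    P <- ad_softmax_rows(ad_scale(ad_matmul(Q, K, tb = TRUE), scale),
                         mask = attn_mask)
    A <- ad_matmul(ad_matmul(P, V), p("Wo"))
    if (dropout > 0) A <- ad_dropout(A, dropout)
    X <- ad_add(X, A)
    H2 <- ad_layernorm(X, p("ln2_g"), p("ln2_b"))
    FF <- ad_add_bias(
      ad_matmul(ad_relu(ad_add_bias(ad_matmul(H2, p("W1")), p("b1"))),
                p("W2")), p("b2"))
    if (dropout > 0) FF <- ad_dropout(FF, dropout)
    X <- ad_add(X, FF)
  }
  ad_layernorm(X, pnodes$lnf_g, pnodes$lnf_b)
}

params_to_leaves <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

#' Encode text to per-wordpiece hidden states (no gradient)
#'
#' @param enc A [new_tiny_encoder()] object.
#' @param words Character vector of word tokens (one sentence).
#' @return List with `states` (pieces x hidden matrix) and the
#'   `encoded_input` used.
#' @export
encode_states <- function(enc, words) {
  ei <- encode_words(enc, words, max_len = enc$max_len)
  tp <- ad_tape()
  pn <- params_to_leaves(tp, enc$params)
  out <- encoder_forward(tp, enc, pn, ei$piece_ids)
  list(states = ad_value(out), encoded = ei)
}
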