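# Span-level evaluation.
#
# Predictions and gold annotations are compared as sets of spans, not as
# per-token labels: IOB sequences are first aggregated into maximal mentions,
# then scored with exact-extent (strict) or >= 1-token-overlap (relaxed)
# matching. Precision/recall/F1 are micro-averaged over all spans by default.

#' Aggregate an IOB label sequence into spans
#'
#' Each maximal `B I I ...` run becomes one span (0-based inclusive token
#' indices). An `I` following `O` or opening the sequence is repaired to `B`
#' (conlleval-style leniency), which affects counts on malformed predictions.
#'
#' @param labels Character vector over `{"O","B","I"}`.
#' @return Data frame with columns `start`, `end`.
#' @export
iob_to_spans <- function(labels) {
  stopifnot(all(labels %in% c("O", "B", "I")))
  n <- length(labels)
  repaired <- labels
  prev <- c("O", labels[-n])
  repaired[labels == "I" & prev == "O"] <- "B"
  starts <- which(repaired == "B")
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ends <- vapply(starts, function(s) {
    e <- s
    while (e < n && repaired[e + 1L] == "I") e <- e + 1L
    e
  }, integer(1))
  data.frame(start = starts - 1L, end = ends - 1L)
}

#' Convert spans back to an IOB sequence
#'
#' @param spans Data frame with `start`, `end` (0-based inclusive).
#' @param n Sentence length in tokens.
#' @return Character vector of IOB labels.
#' @export
spans_to_iob <- function(spans, n) {
  labels <- rep("O", n)
  if (nrow(spans)) {
    for (i in seq_len(nrow(spans))) {
      labels[spans$start[i] + 1L] <- "B"
      if (spans$end[i] > spans$start[i]) {
        labels[(spans$start[i] + 2L):(spans$end[i] + 1L)] <- "I"
      }
    }
  }
  labels
}

span_key_frame <- function(spans) {
  spans <- as.data.frame(spans)
  if (is.null(spans$doc)) spans$doc <- rep("d", nrow(spans))
  if (is.null(spans$sent)) spans$sent <- rep(1L, nrow(spans))
  unique(spans[c("doc", "sent", "start", "end")])
}

span_keys <- function(spans) {
  paste(spans$doc, spans$sent, spans$start, spans$end, sep = "\r")
}

new_eval_report <- function(tp, fp, fn, mode, average = "micro") {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1, mode = mode,
                 average = average,
                 counts = c(tp = tp, fp = fp, fn = fn)),
            class = "eval_report")
}

#' Strict span-level precision / recall / F1
#'
#' A predicted span is a true positive only when its full extent (document,
#' sentence, start, end) exactly equals a gold span. Duplicate identical
#' spans collapse (set semantics). Percentages in \[0, 100\]; the empty
#' denominator convention scores 0.
#'
#' @param gold,pred Data frames of spans with columns `start`, `end` and
#'   optionally `doc`, `sent`.
#' @param average `"micro"` (default, pooled counts) or `"macro"` (mean of
#'   per-document scores).
#' @return An `eval_report`.
#' @export
strict_prf <- function(gold, pred, average = c("micro", "macro")) {
  average <- match.arg(average)
  gold <- span_key_frame(gold); pred <- span_key_frame(pred)
  if (average == "macro") {
    docs <- union(gold$doc, pred$doc)
    reps <- lapply(docs, function(d) {
      strict_prf(gold[gold$doc == d, ], pred[pred$doc == d, ])
    })
    return(macro_pool(reps, "strict"))
  }
  tp <- sum(span_keys(pred) %in% span_keys(gold))
  new_eval_report(tp, nrow(pred) - tp, nrow(gold) - tp, "strict")
}

macro_pool <- function(reps, mode) {
  structure(list(precision = mean(vapply(reps, `[[`, numeric(1), "precision")),
                 recall = mean(vapply(reps, `[[`, numeric(1), "recall")),
                 f1 = mean(vapply(reps, `[[`, numeric(1), "f1")),
                 mode = mode, average = "macro",
                 counts = Reduce(`+`, lapply(reps, `[[`, "counts"))),
            class = "eval_report")
}

#' Relaxed (partial-overlap) span-level precision / recall / F1
#'
#' A predicted span counts as a true positive when it overlaps a gold span of
#' the same document and sentence in at least one token. Matching is
#' one-to-one and greedy — pairs are taken in decreasing overlap size, ties
#' to the leftmost span — so duplicated predictions cannot credit the same
#' gold span twice.
#'
#' @inheritParams strict_prf
#' @return An `eval_report`.
#' @export
relaxed_prf <- function(gold, pred) {
  gold <- span_key_frame(gold); pred <- span_key_frame(pred)
  if (!nrow(gold) || !nrow(pred)) {
    return(new_eval_report(0L, nrow(pred), nrow(gold), "relaxed"))
  }
  ov <- list()
  for (i in seq_len(nrow(pred))) {
    same <- which(gold$doc == pred$doc[i] & gold$sent == pred$sent[i])
    for (j in same) {
      o <- min(pred$end[i], gold$end[j]) - max(pred$start[i], gold$start[j]) + 1L
      if (o > 0L) ov[[length(ov) + 1L]] <- c(i, j, o, pred$start[i])
    }
  }
  tp <- 0L
  if (length(ov)) {
    M <- do.call(rbind, ov)
    M <- M[order(-M[, 3L], M[, 4L], M[, 1L]), , drop = FALSE]
    used_p <- logical(nrow(pred)); used_g <- logical(nrow(gold))
    for (k in seq_len(nrow(M))) {
      i <- M[k, 1L]; j <- M[k, 2L]
      if (!used_p[i] && !used_g[j]) {
        used_p[i] <- TRUE; used_g[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  new_eval_report(tp, nrow(pred) - tp, nrow(gold) - tp, "relaxed")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s span evaluation (%s): P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$mode, x$average, x$precision, x$recall, x$f1))
  cat(sprintf("  tp %d  fp %d  fn %d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"]))
  invisible(x)
}

#' Corpus characterization statistics
#'
#' Per-sentence wordpiece diversity (unique / total wordpieces), sentence
#' length in wordpieces, and knowledge-graph hits (entities found by the
#' lexicon tagger), each averaged over all sentences of the corpus. Special
#' tokens do not count as wordpieces of the sentence.
#'
#' @param corpus An `ade_corpus` (see [generate_corpus()] and the readers).
#' @param tokenizer An object with `venv` (e.g. a [new_tiny_encoder()]).
#' @param lexicon A `kg_lexicon`.
#' @return Object of class `corpus_stats`: list with
#'   `mean_wordpiece_diversity`, `mean_sentence_length`, `mean_kg_hits` and
#'   `n_sentences`.
#' @export
corpus_stats <- function(corpus, tokenizer, lexicon) {
  div <- numeric(0); len <- numeric(0); hits <- numeric(0)
  for (doc in corpus) {
    for (s in doc$sentences) {
      ei <- encode_words(tokenizer, s$tokens)
      body <- ei$wordpieces[!ei$wordpieces %in% c(PAD, CLS, SEP_TOK)]
      if (!length(body)) next
      div <- c(div, length(unique(body)) / length(body))
      len <- c(len, length(body))
      hits <- c(hits, nrow(tag(s$tokens, lexicon)$spans))
    }
  }
  if (!length(len)) stop("empty corpus: no sentences to characterize")
  structure(list(mean_wordpiece_diversity = mean(div),
                 mean_sentence_length = mean(len),
                 mean_kg_hits = mean(hits),
                 n_sentences = length(len)),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(paste0("corpus_stats over %d sentences: diversity %.2f, ",
                     "length %.2f wordpieces, %.2f KG hits\n"),
              x$n_sentences, x$mean_wordpiece_diversity,
              x$mean_sentence_length, x$mean_kg_hits))
  invisible(x)
}
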