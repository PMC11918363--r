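# Graph-concat knowledge fusion.
#
# The fusion model aligns ontology node embeddings to the encoder's wordpiece
# grid and concatenates them with the contextual states before a linear
# three-class IOB head. For each word inside a tagged entity span the span's
# knowledge vector is injected at the word's pivotal (first) wordpiece; every
# other position — remaining pieces, untagged words, special tokens, padding —
# carries exact zeros. Variants: `fixed` (GNN acts as a frozen lookup table),
# `adaptive` (GAT parameters receive gradients from the NER loss), and
# `adaptive_subgraph` (the k-hop neighborhood of each tagged entity is pooled
# by global max plus mean, doubling the knowledge width).

#' Align node embeddings to the wordpiece grid
#'
#' @param ts A `tagged_sequence` (see [tag()]).
#' @param emb A `node_embedding_table`.
#' @param enc An `encoded_input` covering the same words (see
#'   [encode_words()]).
#' @return A pieces x d_G matrix of class `knowledge_vector`; nonzero only at
#'   pivotal pieces of words inside tagged spans.
#' @export
align_knowledge <- function(ts, emb, enc) {
  V <- matrix(0, length(enc$wordpieces), emb$dim)
  if (nrow(ts$spans)) {
    for (i in seq_len(nrow(ts$spans))) {
      node <- ts$spans$node[i]
      if (!node %in% rownames(emb$vectors)) {
        stop("node missing from embedding table: ", node)
      }
      for (w in seq(ts$spans$start[i] + 1L, ts$spans$end[i] + 1L)) {
        r <- enc$word_to_pieces[[w]]
        if (!is.null(r)) V[r[1], ] <- emb$vectors[node, ]
      }
    }
  }
  structure(V, class = c("knowledge_vector", class(V)))
}

#' Concatenate encoder states with the aligned knowledge vector
#'
#' @param T_states Pieces x d_T matrix of encoder states.
#' @param v A `knowledge_vector` (pieces x d_G) of equal length.
#' @return Object of class `fused_representation`: list with `T`, `T_tilde`
#'   (pieces x (d_T + d_G)) and the two widths.
#' @export
fuse <- function(T_states, v) {
  if (nrow(T_states) != nrow(v)) {
    stop("alignment error: ", nrow(T_states), " encoder positions vs ",
         nrow(v), " knowledge positions")
  }
  structure(list(T = T_states, T_tilde = cbind(unclass(T_states), unclass(v)),
                 d_T = ncol(T_states), d_G = ncol(v)),
            class = "fused_representation")
}

# Undirected k-hop neighborhood of a node with the induced edge set,
# expressed in local indices (node of interest first in `ids`).
khop_subgraph <- function(g, node, k) {
  ig <- as_igraph(g)
  ids <- names(igraph::ego(ig, order = k, nodes = node, mode = "all")[[1]])
  ids <- c(node, sort(setdiff(ids, node)))
  keep <- g$edges[, "child"] %in% ids & g$edges[, "parent"] %in% ids
  sub <- g$edges[keep, , drop = FALSE]
  idx <- structure(seq_along(ids), names = ids)
  list(ids = ids,
       edges = cbind(unname(idx[sub[, "child"]]),
                     unname(idx[sub[, "parent"]])))
}

subgraph_edge_index <- function(sub) {
  n <- length(sub$ids)
  if (nrow(sub$edges)) {
    s <- c(sub$edges[, 1L], sub$edges[, 2L])
    d <- c(sub$edges[, 2L], sub$edges[, 1L])
    keep <- !duplicated(cbind(s, d))
    s <- s[keep]; d <- d[keep]
  } else {
    s <- integer(0); d <- integer(0)
  }
  list(src = c(s, seq_len(n)), dst = c(d, seq_len(n)), n = n)
}

#' Pool the k-hop subgraph of a tagged entity
#'
#' Runs the GAT over the k-hop neighborhood (ignoring edge direction) of a
#' node and returns the concatenation of global max and global mean pooling
#' over the subgraph's node representations.
#'
#' @param g An `ontology_graph`.
#' @param node Node identifier.
#' @param gat A `gat_fit`.
#' @param feats A `node_feature_table`.
#' @param k Hop radius.
#' @return Numeric vector of length `2 * d_G`.
#' @export
subgraph_pool <- function(g, node, gat, feats, k = 2L) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  sub <- khop_subgraph(g, node, k)
  ei <- subgraph_edge_index(sub)
  tp <- ad_tape()
  pn <- params_to_leaves(tp, gat$params)
  Z <- gat_forward(tp, gat$cfg, pn, feats$vectors[sub$ids, , drop = FALSE],
                   ei, dropout = 0)
  pooled_subgraph_value(ad_value(Z))
}

pooled_subgraph_value <- function(Z) {
  c(apply(Z, 2L, max), colMeans(Z))
}

#' Assemble a (possibly knowledge-fused) IOB sequence labeler
#'
#' @param encoder A [new_tiny_encoder()].
#' @param variant `"baseline"` (no knowledge), `"fixed"`, `"adaptive"` or
#'   `"adaptive_subgraph"`.
#' @param knowledge For the fusion variants, a list with `lexicon` (a
#'   `kg_lexicon`), and either `embeddings` (a `node_embedding_table`; enough
#'   for `fixed`) or `gat` (a `gat_fit`), `graph` (the `ontology_graph`) and
#'   `feats` (a `node_feature_table`) for the adaptive variants.
#' @param k Hop radius, used only by `adaptive_subgraph`.
#' @param head_dropout Dropout between the fused representation and the
#'   linear head during training.
#' @param seed Seed for the head initialization.
#' @return Object of class `kgfuse_ner`.
#' @export
new_ner_model <- function(encoder, variant = c("baseline", "fixed",
                                               "adaptive",
                                               "adaptive_subgraph"),
                          knowledge = NULL, k = 2L, head_dropout = 0.1,
                          seed = 1L) {
  variant <- match.arg(variant)
  if (variant != "baseline") {
    if (is.null(knowledge$lexicon)) {
      stop("config error: fusion variants need knowledge$lexicon")
    }
    if (variant == "fixed" && is.null(knowledge$embeddings) &&
        is.null(knowledge$gat)) {
      stop("config error: fixed variant needs an embedding table or gat fit")
    }
    if (variant %in% c("adaptive", "adaptive_subgraph") &&
        (is.null(knowledge$gat) || is.null(knowledge$feats))) {
      stop("config error: adaptive variants need knowledge$gat and ",
           "knowledge$feats")
    }
    if (variant == "adaptive_subgraph" && is.null(knowledge$graph)) {
      stop("config error: adaptive_subgraph needs knowledge$graph")
    }
    if (variant == "fixed" && is.null(knowledge$embeddings)) {
      knowledge$embeddings <- knowledge$gat$embeddings
    }
  } else if (!is.null(knowledge)) {
    stop("config error: baseline takes no knowledge source")
  }
  d_G <- if (variant == "baseline") 0L
  else if (!is.null(knowledge$embeddings)) knowledge$embeddings$dim
  else knowledge$gat$cfg$embedding_dim
  d_in <- encoder$hidden +
    switch(variant, baseline = 0L, fixed = d_G, adaptive = d_G,
           adaptive_subgraph = 2L * d_G)
  set.seed(seed + 90001L)
  head <- list(Wh = rmat(d_in, 3L, 1 / sqrt(d_in)), bh = matrix(0, 1L, 3L))
  structure(list(encoder = encoder, head = head, variant = variant,
                 knowledge = knowledge, k = k, d_G = d_G, d_in = d_in,
                 head_dropout = head_dropout, seed = seed),
            class = "kgfuse_ner")
}

#' @export
print.kgfuse_ner <- function(x, ...) {
  cat(sprintf("kgfuse_ner (%s): d_T %d + knowledge %d -> 3-class IOB head\n",
              x$variant, x$encoder$hidden, x$d_in - x$encoder$hidden))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best val strict F1 %.2f%% (epoch %d)\n",
                nrow(x$history), max(x$history$val_f1), x$best_epoch))
  }
  invisible(x)
}

#' @export
coef.kgfuse_ner <- function(object, ...) {
  c(object$encoder$params, object$head,
    if (object$variant %in% c("adaptive", "adaptive_subgraph"))
      object$knowledge$gat$params)
}

# Trainable parameter set per variant; fixed keeps the GNN out, so its
# parameters can receive no gradient by construction.
ner_trainable_params <- function(model) {
  p <- c(model$encoder$params, model$head)
  if (model$variant %in% c("adaptive", "adaptive_subgraph")) {
    p <- c(p, model$knowledge$gat$params)
  }
  p
}

ner_write_back <- function(model, params) {
  enc_names <- names(model$encoder$params)
  model$encoder$params <- params[enc_names]
  model$head <- params[c("Wh", "bh")]
  if (model$variant %in% c("adaptive", "adaptive_subgraph")) {
    gat_names <- names(model$knowledge$gat$params)
    model$knowledge$gat$params <- params[gat_names]
  }
  model
}

# Per-sentence preprocessing shared by training and prediction: wordpiece
# encoding, lexicon tagging, pivot bookkeeping and (for `fixed`) the constant
# knowledge vector.
prepare_sentence <- function(model, words, labels = NULL) {
  enc <- encode_words(model$encoder, words, max_len = model$encoder$max_len)
  np <- length(enc$wordpieces)
  target <- rep(NA_integer_, np)
  pivots <- vapply(enc$word_to_pieces, function(r) {
    if (is.null(r)) NA_integer_ else r[1]
  }, integer(1))
  if (!is.null(labels)) {
    li <- match(labels, c("O", "B", "I"))
    ok <- !is.na(pivots)
    target[pivots[ok]] <- li[ok]
  }
  out <- list(words = words, enc = enc, target = target, pivots = pivots)
  if (model$variant != "baseline") {
    ts <- tag(words, model$knowledge$lexicon)
    out$tagged <- ts
    # Pivot positions and graph node index per tagged word.
    if (nrow(ts$spans)) {
      pw <- list()
      for (i in seq_len(nrow(ts$spans))) {
        for (w in seq(ts$spans$start[i] + 1L, ts$spans$end[i] + 1L)) {
          if (!is.na(pivots[w])) {
            pw[[length(pw) + 1L]] <- c(pivots[w],
                                       span_node_index(model, ts$spans$node[i]))
          }
        }
      }
      out$kpos <- do.call(rbind, pw)
    }
    if (model$variant == "fixed") {
      emb <- model$knowledge$embeddings
      out$v_fixed <- unclass(align_knowledge(ts, emb, enc))
    }
    if (model$variant == "adaptive_subgraph" && !is.null(out$kpos)) {
      out$subgraphs <- lapply(unique(out$kpos[, 2L]), function(ni) {
        node <- model$knowledge$gat$node_ids[ni]
        sub <- khop_subgraph(model$knowledge$graph, node, model$k)
        list(node_index = ni, ids = sub$ids,
             ei = subgraph_edge_index(sub))
      })
    }
  }
  out
}

span_node_index <- function(model, node) {
  ids <- if (!is.null(model$knowledge$gat)) model$knowledge$gat$node_ids
  else rownames(model$knowledge$embeddings$vectors)
  i <- match(node, ids)
  if (is.na(i)) stop("node missing from embedding table: ", node)
  i
}

# Forward pass of one prepared sentence on a tape. Z is the tape node of the
# full-graph GAT embeddings (adaptive variant) or NULL.
ner_sentence_logits <- function(tape, model, pnodes, prep, Z = NULL,
                                train = FALSE) {
  T_node <- encoder_forward(tape, model$encoder, pnodes, prep$enc$piece_ids,
                            dropout = if (train) 0.1 else 0)
  np <- length(prep$enc$wordpieces)
  H <- T_node
  if (model$variant == "fixed") {
    H <- ad_cbind(T_node, ad_leaf(tape, prep$v_fixed))
  } else if (model$variant == "adaptive") {
    H <- ad_cbind(T_node, knowledge_node(tape, model, prep, Z))
  } else if (model$variant == "adaptive_subgraph") {
    H <- ad_cbind(T_node, subgraph_knowledge_node(tape, model, pnodes, prep))
  }
  if (train && model$head_dropout > 0) H <- ad_dropout(H, model$head_dropout)
  ad_add_bias(ad_matmul(H, pnodes$Wh), pnodes$bh)
}

knowledge_node <- function(tape, model, prep, Z) {
  np <- length(prep$enc$wordpieces)
  if (is.null(prep$kpos)) {
    return(ad_leaf(tape, matrix(0, np, model$d_G)))
  }
  ad_scatter_rows(ad_rows(Z, prep$kpos[, 2L]), prep$kpos[, 1L], np)
}

subgraph_knowledge_node <- function(tape, model, pnodes, prep) {
  np <- length(prep$enc$wordpieces)
  if (is.null(prep$kpos)) {
    return(ad_leaf(tape, matrix(0, np, 2L * model$d_G)))
  }
  feats <- model$knowledge$feats$vectors
  pooled <- list()
  for (sg in prep$subgraphs) {
    Zs <- gat_forward(tape, model$knowledge$gat$cfg, pnodes,
                      feats[sg$ids, , drop = FALSE], sg$ei, dropout = 0)
    pooled[[as.character(sg$node_index)]] <-
      ad_cbind(ad_max_rows(Zs), ad_mean_rows(Zs))
  }
  rows <- lapply(seq_len(nrow(prep$kpos)), function(i) {
    pooled[[as.character(prep$kpos[i, 2L])]]
  })
  stacked <- rows[[1]]
  if (length(rows) > 1L) {
    for (i in seq(2L, length(rows))) {
      stacked <- ad_rbind2(stacked, rows[[i]])
    }
  }
  ad_scatter_rows(stacked, prep$kpos[, 1L], np)
}

# rbind of two tape nodes (used only by the subgraph variant).
ad_rbind2 <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  na <- nrow(A)
  ad_new(a$tape, rbind(A, B), c(a$id, b$id), function(G) {
    list(G[seq_len(na), , drop = FALSE], G[-seq_len(na), , drop = FALSE])
  })
}

# Full-graph GAT embeddings as a tape node (adaptive variant).
adaptive_graph_node <- function(tape, model, pnodes) {
  gat <- model$knowledge$gat
  gat_forward(tape, gat$cfg, pnodes, model$knowledge$feats$vectors,
              gat$edge_index, dropout = 0)
}

#' Per-wordpiece IOB logits for raw sentences
#'
#' @param model A `kgfuse_ner`.
#' @param sentences List of word-token character vectors.
#' @return List of pieces x 3 logit matrices (classes O, B, I).
#' @export
ner_logits <- function(model, sentences) {
  tp <- ad_tape()
  pnodes <- params_to_leaves(tp, ner_trainable_params(model))
  Z <- if (model$variant == "adaptive") adaptive_graph_node(tp, model, pnodes)
  lapply(sentences, function(words) {
    prep <- prepare_sentence(model, words)
    ad_value(ner_sentence_logits(tp, model, pnodes, prep, Z))
  })
}

#' Predict ADE spans for a corpus
#'
#' Labels are read at each word's pivotal wordpiece and aggregated to spans.
#'
#' @param object A trained `kgfuse_ner`.
#' @param corpus An `ade_corpus`.
#' @param ... Unused.
#' @return List with `spans` (data frame `doc`, `sent`, `start`, `end`) and
#'   `labels` (per doc, per sentence IOB vectors).
#' @export
predict.kgfuse_ner <- function(object, corpus, ...) {
  tp <- ad_tape()
  pnodes <- params_to_leaves(tp, ner_trainable_params(object))
  Z <- if (object$variant == "adaptive")
    adaptive_graph_node(tp, object, pnodes)
  all_spans <- list(); all_labels <- list()
  for (doc in corpus) {
    doc_labels <- list()
    for (k in seq_along(doc$sentences)) {
      words <- doc$sentences[[k]]$tokens
      if (!length(words)) { doc_labels[[k]] <- character(0); next }
      prep <- prepare_sentence(object, words)
      logits <- ad_value(ner_sentence_logits(tp, object, pnodes, prep, Z))
      lab <- rep("O", length(words))
      ok <- !is.na(prep$pivots)
      lab[ok] <- c("O", "B", "I")[max.col(logits[prep$pivots[ok], ,
                                                 drop = FALSE],
                                          ties.method = "first")]
      doc_labels[[k]] <- lab
      sp <- iob_to_spans(lab)
      if (nrow(sp)) {
        sp$doc <- doc$id; sp$sent <- k
        all_spans[[length(all_spans) + 1L]] <- sp
      }
    }
    all_labels[[doc$id]] <- doc_labels
  }
  spans <- if (length(all_spans)) {
    do.call(rbind, all_spans)[c("doc", "sent", "start", "end")]
  } else {
    data.frame(doc = character(0), sent = integer(0), start = integer(0),
               end = integer(0))
  }
  list(spans = spans, labels = all_labels)
}
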