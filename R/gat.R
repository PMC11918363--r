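# Graph attention network over the ontology graph.
#
# Node features are sentence embeddings of each class's annotation text
# (label, synonyms, definition) produced by a contextual text encoder; the
# GAT is then trained either to predict each node's top-level branch (node
# classification, the default) or to score held-out subclass edges (link
# prediction). The activations of the last GAT layer — before the linear
# classifier head — are exported as the node embedding table consumed by the
# fusion models. Attention lets a node down-weight neighbors whose classes
# carry little annotation text.

#' Assemble the annotation text of an ontology class
#'
#' Deterministic concatenation: label, then synonyms in input order, then the
#' definition, joined by a single `[SEP]` separator token; falls back to the
#' class identifier when every annotation is empty.
#'
#' @param cls A class record (element of `ontology_graph$classes`).
#' @return A single string.
#' @export
assemble_node_text <- function(cls) {
  seg <- c(cls$label, cls$synonyms, cls$definition)
  seg <- seg[nzchar(seg)]
  if (!length(seg)) return(cls$id)
  paste(seg, collapse = " [SEP] ")
}

#' Encode node features for every class of a graph
#'
#' Each node's feature vector is the mean over the final-layer wordpiece
#' states of its assembled annotation text, so the feature dimensionality
#' equals the encoder hidden size.
#'
#' @param g An `ontology_graph`.
#' @param encoder A [new_tiny_encoder()] (or any object usable with
#'   [encode_states()]).
#' @return Object of class `node_feature_table`: list with `vectors` (node x
#'   dim matrix, rownames = node ids) and `dim`.
#' @export
encode_node_features <- function(g, encoder) {
  M <- matrix(0, length(g$nodes), encoder$hidden,
              dimnames = list(g$nodes, NULL))
  for (id in g$nodes) {
    words <- strsplit(assemble_node_text(g$classes[[id]]), "\\s+")[[1]]
    st <- encode_states(encoder, words)
    # Mean over the text pieces only, excluding [CLS]/[SEP].
    body <- seq(2L, nrow(st$states) - 1L)
    M[id, ] <- colMeans(st$states[body, , drop = FALSE])
  }
  stopifnot(all(is.finite(M)))
  structure(list(vectors = M, dim = ncol(M)), class = "node_feature_table")
}

#' GAT configuration
#'
#' @param n_layers,n_heads,hidden_dim,embedding_dim,dropout,epochs,
#'   learning_rate,seed Hyperparameters; `embedding_dim` is the exported
#'   embedding dimensionality d_G. `hidden_dim` and `embedding_dim` must be
#'   divisible by `n_heads`.
#' @return A list of class `gat_config`.
#' @export
gat_config <- function(n_layers = 2L, n_heads = 4L, hidden_dim = 64L,
                       embedding_dim = 128L, dropout = 0.2, epochs = 200L,
                       learning_rate = 5e-3, seed = 1L) {
  stopifnot(n_layers >= 1L, n_heads >= 1L, hidden_dim >= 1L,
            embedding_dim >= 1L, dropout >= 0, dropout < 1, epochs >= 0L,
            learning_rate >= 0)
  if (hidden_dim %% n_heads || embedding_dim %% n_heads) {
    stop("hidden_dim and embedding_dim must be divisible by n_heads")
  }
  structure(list(n_layers = n_layers, n_heads = n_heads,
                 hidden_dim = hidden_dim, embedding_dim = embedding_dim,
                 dropout = dropout, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "gat_config")
}

# Message-passing edge index from an ontology graph: child->parent edges are
# symmetrized by default (a directed tree would starve leaf-ward information
# flow) and self-loops are always added.
gat_edge_index <- function(g, bidirectional = TRUE) {
  idx <- structure(seq_along(g$nodes), names = g$nodes)
  src <- idx[g$edges[, "child"]]
  dst <- idx[g$edges[, "parent"]]
  if (bidirectional) {
    s <- c(src, dst); d <- c(dst, src)
  } else {
    s <- src; d <- dst
  }
  keep <- !duplicated(cbind(s, d))
  s <- c(s[keep], seq_along(g$nodes))
  d <- c(d[keep], seq_along(g$nodes))
  list(src = unname(s), dst = unname(d), n = length(g$nodes))
}

gat_layer_dims <- function(cfg, in_dim) {
  outs <- c(rep(cfg$hidden_dim, cfg$n_layers - 1L), cfg$embedding_dim)
  list(ins = c(in_dim, outs[-cfg$n_layers]), outs = outs)
}

gat_init_params <- function(cfg, in_dim, n_classes = NULL) {
  dims <- gat_layer_dims(cfg, in_dim)
  params <- list()
  for (l in seq_len(cfg$n_layers)) {
    dh <- dims$outs[l] / cfg$n_heads
    for (h in seq_len(cfg$n_heads)) {
      pre <- sprintf("g%d_h%d_", l, h)
      params[[paste0(pre, "W")]] <- rmat(dims$ins[l], dh, 1 / sqrt(dims$ins[l]))
      params[[paste0(pre, "as")]] <- rmat(dh, 1L, 0.2)
      params[[paste0(pre, "ad")]] <- rmat(dh, 1L, 0.2)
    }
  }
  if (!is.null(n_classes)) {
    params$Wc <- rmat(cfg$embedding_dim, n_classes,
                      1 / sqrt(cfg$embedding_dim))
    params$bc <- matrix(0, 1L, n_classes)
  }
  params
}

# Forward pass on a tape; returns the embedding node (n x d_G). feats may be
# a plain matrix (turned into a constant leaf) or an existing tape node.
gat_forward <- function(tape, cfg, pnodes, feats, ei, dropout = 0) {
  H <- if (inherits(feats, "adnode")) feats else ad_leaf(tape, feats)
  for (l in seq_len(cfg$n_layers)) {
    heads <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      pre <- sprintf("g%d_h%d_", l, h)
      HW <- ad_matmul(H, pnodes[[paste0(pre, "W")]])
      ssrc <- ad_matmul(HW, pnodes[[paste0(pre, "as")]])
      sdst <- ad_matmul(HW, pnodes[[paste0(pre, "ad")]])
      e <- ad_leaky_relu(ad_add(ad_rows(ssrc, ei$src),
                                ad_rows(sdst, ei$dst)), 0.2)
      alpha <- ad_segment_softmax(e, ei$dst, ei$n)
      if (dropout > 0) alpha <- ad_dropout(alpha, dropout)
      msg <- ad_colscale(ad_rows(HW, ei$src), alpha)
      heads[[h]] <- ad_rowsum_segments(msg, ei$dst, ei$n)
    }
    H <- heads[[1]]
    if (cfg$n_heads > 1L) {
      for (h in seq(2L, cfg$n_heads)) H <- ad_cbind(H, heads[[h]])
    }
    H <- ad_elu(H)
  }
  H
}

# Per-head attention coefficients of the first layer on a plain forward pass;
# used by tests to check they normalize within each in-neighborhood.
gat_attention_coefficients <- function(fit, feats, ei) {
  tp <- ad_tape()
  pn <- params_to_leaves(tp, fit$params)
  H <- ad_leaf(tp, feats)
  out <- matrix(0, length(ei$src), fit$cfg$n_heads)
  for (h in seq_len(fit$cfg$n_heads)) {
    pre <- sprintf("g1_h%d_", h)
    HW <- ad_matmul(H, pn[[paste0(pre, "W")]])
    ssrc <- ad_matmul(HW, pn[[paste0(pre, "as")]])
    sdst <- ad_matmul(HW, pn[[paste0(pre, "ad")]])
    e <- ad_leaky_relu(ad_add(ad_rows(ssrc, ei$src),
                              ad_rows(sdst, ei$dst)), 0.2)
    out[, h] <- ad_value(ad_segment_softmax(e, ei$dst, ei$n))
  }
  out
}

new_embedding_table <- function(Z, node_ids, provenance, cfg) {
  rownames(Z) <- node_ids
  structure(list(vectors = Z, dim = ncol(Z), provenance = provenance,
                 seed = cfg$seed,
                 config_hash = paste0("gat-", cfg$n_layers, "x", cfg$n_heads,
                                      "-", cfg$hidden_dim, "-",
                                      cfg$embedding_dim)),
            class = "node_embedding_table")
}

#' @export
print.node_embedding_table <- function(x, ...) {
  cat(sprintf("node_embedding_table: %d nodes, dim %d, provenance %s\n",
              nrow(x$vectors), x$dim, x$provenance))
  invisible(x)
}

#' Train a GAT on top-level node classification
#'
#' Full-batch training with AdamW on the cross-entropy of predicting each
#' non-root node's top-level branch, with a stratified seeded 80/20 node
#' split; the held-out accuracy is recorded in the training report. The
#' exported embeddings are the last GAT layer's activations (before the
#' linear classifier head), taken from a dropout-free forward pass.
#'
#' @param g An `ontology_graph`.
#' @param feats A `node_feature_table` covering all nodes.
#' @param labeling A `top_level_labeling` of `g`.
#' @param cfg A [gat_config()].
#' @param bidirectional Symmetrize edges for message passing (default TRUE).
#' @return Object of class `gat_fit` with elements `params`, `cfg`,
#'   `embeddings` (a `node_embedding_table`), `report` (per-epoch `loss`,
#'   `final_loss`, `holdout_accuracy`), `task`, `edge_index`, `node_ids`.
#' @export
train_gat_node_classification <- function(g, feats, labeling, cfg = gat_config(),
                                          bidirectional = TRUE) {
  if (labeling$n_classes < 2L) {
    stop("degenerate task: need at least 2 top-level classes")
  }
  X <- feats$vectors[g$nodes, , drop = FALSE]
  if (!all(g$nodes %in% rownames(feats$vectors))) {
    stop("feature table does not cover all graph nodes")
  }
  ei <- gat_edge_index(g, bidirectional)
  set.seed(cfg$seed)
  params <- gat_init_params(cfg, ncol(X), labeling$n_classes)
  # Targets: 1-based class index per node, NA for the root (excluded).
  y <- rep(NA_integer_, length(g$nodes))
  pos <- match(names(labeling$labels), g$nodes)
  y[pos] <- as.integer(labeling$labels) + 1L
  labeled <- which(!is.na(y))
  # Stratified 80/20 split over labeled nodes.
  holdout <- unlist(lapply(split(labeled, y[labeled]), function(ix) {
    k <- max(1L, round(0.2 * length(ix)))
    if (length(ix) == 1L) integer(0) else sample(ix, k)
  }), use.names = FALSE)
  train_ix <- setdiff(labeled, holdout)
  y_train <- y; y_train[holdout] <- NA_integer_
  opt <- adamw_init(params)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    tp <- ad_tape()
    pn <- params_to_leaves(tp, params)
    Z <- gat_forward(tp, cfg, pn, X, ei, dropout = cfg$dropout)
    logits <- ad_add_bias(ad_matmul(Z, pn$Wc), pn$bc)
    loss <- ad_softmax_xent(logits, y_train)
    ad_backward(loss)
    losses[ep] <- ad_value(loss)
    grads <- lapply(pn, ad_grad)
    st <- adamw_step(params, grads, opt, lr = cfg$learning_rate,
                     weight_decay = 5e-4)
    params <- st$params; opt <- st$state
  }
  tp <- ad_tape()
  pn <- params_to_leaves(tp, params)
  Z <- gat_forward(tp, cfg, pn, X, ei, dropout = 0)
  logits <- ad_value(ad_add_bias(ad_matmul(Z, pn$Wc), pn$bc))
  pred <- max.col(logits, ties.method = "first")
  acc <- if (length(holdout)) mean(pred[holdout] == y[holdout]) else NA_real_
  structure(list(params = params, cfg = cfg,
                 embeddings = new_embedding_table(ad_value(Z), g$nodes,
                                                  "node_classification", cfg),
                 report = list(loss = losses,
                               final_loss = if (cfg$epochs) losses[cfg$epochs]
                                            else NA_real_,
                               holdout_accuracy = acc,
                               holdout_majority = if (length(train_ix))
                                 max(table(y[train_ix])) / length(train_ix)
                                 else NA_real_),
                 task = "node_classification", edge_index = ei,
                 node_ids = g$nodes, in_dim = ncol(X)),
            class = "gat_fit")
}

#' Train a GAT on link prediction
#'
#' Alternative training task: 10\% of the subclass edges are held out of the
#' training objective, and node-pair scores are dot products of embeddings
#' trained with binary cross-entropy against uniformly sampled negative
#' pairs (1:1). Message passing runs over the full (symmetrized) edge set:
#' on a tree-shaped knowledge graph every edge is a bridge, so removing the
#' held-out edges from propagation would disconnect exactly the node pairs
#' being ranked and leave them nothing to be scored from. The report
#' carries the ranking AUC of held-out edges against sampled negatives.
#'
#' @inheritParams train_gat_node_classification
#' @return A `gat_fit` with `task = "link_prediction"` and `report$auc`.
#' @export
train_gat_link_prediction <- function(g, feats, cfg = gat_config(),
                                      bidirectional = TRUE) {
  if (nrow(g$edges) < 10L) stop("need at least 10 edges for link prediction")
  X <- feats$vectors[g$nodes, , drop = FALSE]
  idx <- structure(seq_along(g$nodes), names = g$nodes)
  E <- cbind(idx[g$edges[, "child"]], idx[g$edges[, "parent"]])
  set.seed(cfg$seed)
  hold <- sample(nrow(E), max(1L, round(0.1 * nrow(E))))
  Etr <- E[-hold, , drop = FALSE]
  ei <- gat_edge_index(g, bidirectional)
  params <- gat_init_params(cfg, ncol(X))
  opt <- adamw_init(params)
  n <- length(g$nodes)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    neg <- cbind(sample(n, nrow(Etr), replace = TRUE),
                 sample(n, nrow(Etr), replace = TRUE))
    pairs <- rbind(Etr, neg)
    lab <- rep(c(1, 0), each = nrow(Etr))
    tp <- ad_tape()
    pn <- params_to_leaves(tp, params)
    Z <- gat_forward(tp, cfg, pn, X, ei, dropout = cfg$dropout)
    prod <- ad_mul(ad_rows(Z, pairs[, 1L]), ad_rows(Z, pairs[, 2L]))
    score <- ad_matmul(prod, ad_leaf(tp, matrix(1, ncol(ad_value(Z)), 1L)))
    loss <- ad_bce_logits(score, lab)
    ad_backward(loss)
    losses[ep] <- ad_value(loss)
    grads <- lapply(pn, ad_grad)
    st <- adamw_step(params, grads, opt, lr = cfg$learning_rate,
                     weight_decay = 5e-4)
    params <- st$params; opt <- st$state
  }
  tp <- ad_tape()
  pn <- params_to_leaves(tp, params)
  Zv <- ad_value(gat_forward(tp, cfg, pn, X, ei, dropout = 0))
  pos_sc <- rowSums(Zv[E[hold, 1L], , drop = FALSE] *
                      Zv[E[hold, 2L], , drop = FALSE])
  negev <- cbind(sample(n, 10L * length(hold), replace = TRUE),
                 sample(n, 10L * length(hold), replace = TRUE))
  neg_sc <- rowSums(Zv[negev[, 1L], , drop = FALSE] *
                      Zv[negev[, 2L], , drop = FALSE])
  # Wilcoxon/Mann-Whitney form of the ranking AUC.
  r <- rank(c(pos_sc, neg_sc))
  auc <- (sum(r[seq_along(pos_sc)]) -
            length(pos_sc) * (length(pos_sc) + 1) / 2) /
    (length(pos_sc) * length(neg_sc))
  structure(list(params = params, cfg = cfg,
                 embeddings = new_embedding_table(Zv, g$nodes,
                                                  "link_prediction", cfg),
                 report = list(loss = losses,
                               final_loss = if (cfg$epochs) losses[cfg$epochs]
                                            else NA_real_,
                               auc = auc),
                 task = "link_prediction", edge_index = ei,
                 node_ids = g$nodes, in_dim = ncol(X)),
            class = "gat_fit")
}

#' @export
print.gat_fit <- function(x, ...) {
  cat(sprintf("gat_fit (%s): %d nodes, d_G = %d\n", x$task,
              length(x$node_ids), x$cfg$embedding_dim))
  if (!is.null(x$report$holdout_accuracy)) {
    cat(sprintf("  final loss %.4f, held-out accuracy %s\n",
                x$report$final_loss,
                format(x$report$holdout_accuracy, digits = 3)))
  }
  if (!is.null(x$report$auc)) {
    cat(sprintf("  final loss %.4f, held-out AUC %.3f\n",
                x$report$final_loss, x$report$auc))
  }
  invisible(x)
}

#' @export
coef.gat_fit <- function(object, ...) object$params

#' Write / read a node embedding table
#'
#' Stored as a TSV (`node_id` TAB comma-separated floats) plus a JSON
#' metadata header with the dimension, provenance, seed and config hash.
#'
#' @param emb A `node_embedding_table`.
#' @param dir Target directory.
#' @return `write_embeddings` returns `dir` invisibly; `read_embeddings` the
#'   reloaded table.
#' @export
write_embeddings <- function(emb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(seq_len(nrow(emb$vectors)), function(i) {
    paste0(rownames(emb$vectors)[i], "\t",
           paste(format(emb$vectors[i, ], digits = 17, scientific = TRUE,
                        trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(rows, file.path(dir, "embeddings.tsv"))
  jsonlite::write_json(list(dim = emb$dim, provenance = emb$provenance,
                            seed = emb$seed, config_hash = emb$config_hash),
                       file.path(dir, "embeddings.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "embeddings.json"))
  rows <- strsplit(readLines(file.path(dir, "embeddings.tsv")), "\t",
                   fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1L)
  M <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(r[2L], ",", fixed = TRUE)[[1]])
  }))
  rownames(M) <- ids
  structure(list(vectors = M, dim = meta$dim, provenance = meta$provenance,
                 seed = meta$seed, config_hash = meta$config_hash),
            class = "node_embedding_table")
}
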