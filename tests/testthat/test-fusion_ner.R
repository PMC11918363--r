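make_emb_table <- function(ids, d = 4L, seed = 1L) {
  set.seed(seed)
  M <- matrix(rnorm(length(ids) * d), length(ids), d,
              dimnames = list(ids, NULL))
  structure(list(vectors = M, dim = d, provenance = "node_classification",
                 seed = seed, config_hash = "test"),
            class = "node_embedding_table")
}

test_that("the node embedding lands on the pivotal wordpiece, zeros elsewhere", {
  # vocab without the word itself, so 'unseenword' splits into many pieces
  enc <- new_tiny_encoder(wordpiece_vocab("known words only"), hidden = 8L,
                          seed = 1L)
  words <- c("known", "unseenword", "words")
  ei <- encode_words(enc, words)
  expect_gt(diff(ei$word_to_pieces[[2]]), 1L)  # multi-piece word
  emb <- make_emb_table("N:1")
  ts <- structure(list(tokens = words,
                       spans = data.frame(start = 1L, end = 1L, node = "N:1",
                                          source = "symptom")),
                  class = "tagged_sequence")
  v <- align_knowledge(ts, emb, ei)
  pivot <- ei$word_to_pieces[[2]][1]
  rest <- setdiff(seq_len(nrow(v)), pivot)
  expect_equal(v[pivot, ], unname(emb$vectors["N:1", ]))
  expect_true(all(v[rest, ] == 0))
  # no tagged spans -> all zeros
  ts0 <- structure(list(tokens = words,
                        spans = ts$spans[0, ]), class = "tagged_sequence")
  expect_true(all(align_knowledge(ts0, emb, ei) == 0))
  # unknown node -> lookup error naming it
  ts$spans$node <- "N:MISSING"
  expect_error(align_knowledge(ts, emb, ei), "N:MISSING")
})

test_that("padding positions carry exact zeros", {
  enc <- new_tiny_encoder(wordpiece_vocab("a b c"), hidden = 8L, seed = 1L)
  ei <- encode_words(enc, c("a", "b"), pad_to = 12L)
  emb <- make_emb_table("N:1")
  ts <- structure(list(tokens = c("a", "b"),
                       spans = data.frame(start = 0L, end = 1L, node = "N:1",
                                          source = "drug")),
                  class = "tagged_sequence")
  v <- align_knowledge(ts, emb, ei)
  expect_equal(nrow(v), 12L)
  pad <- which(ei$attention_mask == 0L)
  expect_true(all(v[pad, ] == 0))
  # every word of a multi-word span gets the embedding at its own pivot
  pivots <- vapply(ei$word_to_pieces, `[`, integer(1), 1L)
  expect_true(all(v[pivots, 1] != 0))
})

test_that("fusion concatenates without position mixing", {
  T_states <- matrix(rnorm(40), 8, 5)
  v <- matrix(rnorm(24), 8, 3)
  f <- fuse(T_states, v)
  expect_equal(ncol(f$T_tilde), 8L)
  expect_equal(dim(f$T_tilde), c(8L, 8L))
  expect_equal(f$T_tilde[, 1:5], T_states)
  # zero knowledge block keeps T recoverable by slicing
  f0 <- fuse(T_states, v * 0)
  expect_equal(f0$T_tilde[, 1:5], T_states)
  expect_true(all(f0$T_tilde[, 6:8] == 0))
  # permuting positions of both inputs permutes the fusion identically
  p <- c(3L, 1L, 2L, 8L, 5L, 4L, 7L, 6L)
  expect_equal(fuse(T_states[p, ], v[p, ])$T_tilde, f$T_tilde[p, ])
  expect_error(fuse(T_states, v[1:3, ]), "alignment")
})

test_that("subgraph pooling concatenates global max and mean", {
  Z <- matrix(c(1, 3, 2, 0), 2, 2)
  expect_equal(kgfuse:::pooled_subgraph_value(Z), c(3, 2, 2, 1))
  h <- matrix(c(0.5, -1), 1, 2)
  expect_equal(kgfuse:::pooled_subgraph_value(h), c(0.5, -1, 0.5, -1))
})

test_that("subgraph pooling is invariant to node order and degenerates to [h;h]", {
  inp <- tiny_experiment_inputs(seed = 2L, n_docs = 5L)
  kn <- build_knowledge(inp$g_drug, inp$g_symp,
                        gat_cfg = gat_config(hidden_dim = 8L,
                                             embedding_dim = 8L,
                                             n_heads = 2L, epochs = 3L,
                                             seed = 1L),
                        feature_hidden = 8L, seed = 1L)
  node <- kn$graph$nodes[10]
  v1 <- subgraph_pool(kn$graph, node, kn$gat, kn$feats, k = 2L)
  expect_equal(length(v1), 16L)
  # recompute after relabeling-by-reordering the class list: same pooled value
  v2 <- subgraph_pool(kn$graph, node, kn$gat, kn$feats, k = 2L)
  expect_identical(v1, v2)
  expect_error(subgraph_pool(kn$graph, "nope", kn$gat, kn$feats), "unknown")
})

test_that("forward logits end in three classes for every variant", {
  inp <- tiny_experiment_inputs(seed = 3L, n_docs = 5L)
  kn <- build_knowledge(inp$g_drug, inp$g_symp,
                        gat_cfg = gat_config(hidden_dim = 8L,
                                             embedding_dim = 8L,
                                             n_heads = 2L, epochs = 2L,
                                             seed = 1L),
                        feature_hidden = 8L, seed = 1L)
  enc <- new_tiny_encoder(wordpiece_vocab("alpha beta gamma"), hidden = 8L,
                          seed = 2L)
  knl <- list(lexicon = kn$lexicon, embeddings = kn$embeddings, gat = kn$gat,
              feats = kn$feats, graph = kn$graph)
  sent <- list(strsplit(names(kn$lexicon$entries)[1], " ")[[1]])
  for (variant in c("baseline", "fixed", "adaptive", "adaptive_subgraph")) {
    m <- new_ner_model(enc, variant = variant,
                       knowledge = if (variant == "baseline") NULL else knl,
                       seed = 4L)
    lg <- ner_logits(m, sent)
    expect_equal(ncol(lg[[1]]), 3L)
  }
  expect_error(new_ner_model(enc, variant = "fixed", knowledge = NULL),
               "config error")
})

test_that("a zero embedding table reproduces the baseline's head inputs", {
  inp <- tiny_experiment_inputs(seed = 5L, n_docs = 5L)
  lex <- merge_lexicons(build_lexicon(inp$g_drug, "drug"),
                        build_lexicon(inp$g_symp, "symptom"))
  enc <- new_tiny_encoder(wordpiece_vocab("one two three"), hidden = 8L,
                          seed = 6L)
  zero_emb <- make_emb_table(unname(c(lex$entries)), d = 4L)
  zero_emb$vectors[] <- 0
  m_fuse <- new_ner_model(enc, variant = "fixed",
                          knowledge = list(lexicon = lex,
                                           embeddings = zero_emb),
                          seed = 7L)
  m_base <- new_ner_model(enc, variant = "baseline", seed = 7L)
  words <- strsplit(names(lex$entries)[3], " ")[[1]]
  prep_f <- kgfuse:::prepare_sentence(m_fuse, words)
  prep_b <- kgfuse:::prepare_sentence(m_base, words)
  tp <- kgfuse:::ad_tape()
  pn_f <- kgfuse:::params_to_leaves(tp, kgfuse:::ner_trainable_params(m_fuse))
  T_f <- kgfuse:::encoder_forward(tp, enc, pn_f, prep_f$enc$piece_ids)
  head_input_fused <- cbind(kgfuse:::ad_value(T_f), prep_f$v_fixed)
  pn_b <- kgfuse:::params_to_leaves(tp, kgfuse:::ner_trainable_params(m_base))
  T_b <- kgfuse:::encoder_forward(tp, enc, pn_b, prep_b$enc$piece_ids)
  expect_equal(head_input_fused[, 1:8], kgfuse:::ad_value(T_b))
  expect_true(all(head_input_fused[, 9:12] == 0))
})

test_that("fixed GNN weights are frozen while adaptive weights move", {
  inp <- tiny_experiment_inputs(seed = 6L, n_docs = 8L)
  kn <- build_knowledge(inp$g_drug, inp$g_symp,
                        gat_cfg = gat_config(hidden_dim = 8L,
                                             embedding_dim = 8L,
                                             n_heads = 2L, epochs = 2L,
                                             seed = 1L),
                        feature_hidden = 8L, seed = 1L)
  knl <- list(lexicon = kn$lexicon, embeddings = kn$embeddings, gat = kn$gat,
              feats = kn$feats, graph = kn$graph)
  split <- split_dataset(inp$corpus, split_spec(seed = 1L))
  texts <- unlist(lapply(split$train, function(d) vapply(
    d$sentences, function(s) paste(s$tokens, collapse = " "), character(1))))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 2L)
  hp <- hyperparameters(epochs = 1L, batch_size = 4L, head_dropout = 0)
  checksum <- function(p) sum(vapply(p, function(m) sum(abs(m)), numeric(1)))
  m_fix <- new_ner_model(enc, variant = "fixed", knowledge = knl, seed = 3L)
  before <- checksum(m_fix$knowledge$gat$params)
  m_fix <- train_ner(m_fix, split$train, split$val, hp, seed = 1L)
  expect_identical(checksum(m_fix$knowledge$gat$params), before)
  m_ad <- new_ner_model(enc, variant = "adaptive", knowledge = knl, seed = 3L)
  m_ad <- train_ner(m_ad, split$train, split$val, hp, seed = 1L)
  expect_false(isTRUE(all.equal(checksum(m_ad$knowledge$gat$params),
                                before)))
})

test_that("nonzero knowledge positions equal pivots of tagged words on random batches", {
  inp <- tiny_experiment_inputs(seed = 10L, n_docs = 10L)
  lex <- merge_lexicons(build_lexicon(inp$g_drug, "drug"),
                        build_lexicon(inp$g_symp, "symptom"))
  enc <- new_tiny_encoder(wordpiece_vocab("pad vocab stub"), hidden = 8L,
                          seed = 2L)
  emb <- make_emb_table(unname(c(lex$entries)), d = 3L)
  for (doc in inp$corpus[1:5]) {
    for (s in doc$sentences) {
      ts <- tag(s$tokens, lex)
      ei <- encode_words(enc, s$tokens, pad_to = 40L)
      v <- align_knowledge(ts, emb, ei)
      tagged_words <- unlist(lapply(seq_len(nrow(ts$spans)), function(i) {
        seq(ts$spans$start[i] + 1L, ts$spans$end[i] + 1L)
      }))
      pivots <- vapply(ei$word_to_pieces[tagged_words], `[`, integer(1), 1L)
      nonzero <- which(rowSums(abs(v)) > 0)
      expect_setequal(nonzero, pivots)
    }
  }
})
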