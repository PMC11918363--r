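test_that("node text assembles label, synonyms then definition with separators", {
  cls <- list(id = "S:1", label = "Drowsiness",
              synonyms = c("drowsy", "sleepiness"),
              definition = "reduced wakefulness", parents = character(0))
  expect_equal(assemble_node_text(cls),
               "Drowsiness [SEP] drowsy [SEP] sleepiness [SEP] reduced wakefulness")
  expect_equal(assemble_node_text(list(id = "S:2", label = "Pain",
                                       synonyms = character(0),
                                       definition = "")), "Pain")
  expect_equal(assemble_node_text(list(id = "SYMP:0000001", label = "",
                                       synonyms = character(0),
                                       definition = "")), "SYMP:0000001")
})

test_that("node features pass the encoder hidden size through and are deterministic", {
  g <- toy_symptom_graph()
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc16 <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 16L, seed = 5L)
  ft <- encode_node_features(g, enc16)
  expect_equal(ft$dim, 16L)
  expect_equal(nrow(ft$vectors), n_nodes(g))
  expect_true(all(is.finite(ft$vectors)))
  # identical assembled text -> identical vectors
  g2 <- ontology_graph(list(
    list(id = "R", label = "root", parents = character(0)),
    list(id = "A", label = "same text", parents = "R"),
    list(id = "B", label = "same text", parents = "R")))
  ft2 <- encode_node_features(g2, enc16)
  expect_identical(ft2$vectors["A", ], ft2$vectors["B", ])
})

test_that("attention coefficients normalize within each in-neighborhood", {
  g <- generate_ontology(ontology_spec(n_classes = 12L, n_top = 3L,
                                       seed = 2L))
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 2L)
  ft <- encode_node_features(g, enc)
  fit <- train_gat_node_classification(g, ft, assign_top_level_labels(g),
                                       gat_config(hidden_dim = 8L,
                                                  embedding_dim = 8L,
                                                  n_heads = 2L, epochs = 2L,
                                                  seed = 1L))
  ei <- fit$edge_index
  alpha <- kgfuse:::gat_attention_coefficients(fit, ft$vectors, ei)
  sums <- rowsum(alpha, ei$dst)
  expect_equal(unname(sums), matrix(1, n_nodes(g), 2L), tolerance = 1e-10)
})

test_that("node-classification training is seed-reproducible and exports all nodes", {
  g <- generate_ontology(ontology_spec(n_classes = 30L, n_top = 3L,
                                       seed = 6L))
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 3L)
  ft <- encode_node_features(g, enc)
  lab <- assign_top_level_labels(g)
  cfg <- gat_config(hidden_dim = 8L, embedding_dim = 8L, n_heads = 2L,
                    epochs = 10L, seed = 4L)
  f1 <- train_gat_node_classification(g, ft, lab, cfg)
  f2 <- train_gat_node_classification(g, ft, lab, cfg)
  expect_identical(f1$embeddings$vectors, f2$embeddings$vectors)
  expect_setequal(rownames(f1$embeddings$vectors), g$nodes)
  expect_equal(length(f1$report$loss), 10L)
  # fewer than two classes is a degenerate task
  chain <- ontology_graph(list(
    list(id = "R", label = "r", parents = character(0)),
    list(id = "a", label = "a", parents = "R"),
    list(id = "b", label = "b", parents = "a")))
  expect_error(train_gat_node_classification(
    chain, encode_node_features(chain, enc),
    assign_top_level_labels(chain), cfg), "degenerate")
})

test_that("zero learning-rate training returns the seeded initial forward pass", {
  g <- generate_ontology(ontology_spec(n_classes = 20L, n_top = 2L,
                                       seed = 8L))
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 3L)
  ft <- encode_node_features(g, enc)
  lab <- assign_top_level_labels(g)
  mk <- function() gat_config(hidden_dim = 8L, embedding_dim = 8L,
                              n_heads = 2L, epochs = 1L, dropout = 0,
                              learning_rate = 0, seed = 9L)
  f1 <- train_gat_node_classification(g, ft, lab, mk())
  f2 <- train_gat_node_classification(g, ft, lab, mk())
  expect_identical(f1$embeddings$vectors, f2$embeddings$vectors)
  # and equals the plain forward pass of the seeded initial parameters
  set.seed(9L)
  params <- kgfuse:::gat_init_params(mk(), ncol(ft$vectors), lab$n_classes)
  tp <- kgfuse:::ad_tape()
  pn <- kgfuse:::params_to_leaves(tp, params)
  Z <- kgfuse:::gat_forward(tp, mk(), pn, ft$vectors[g$nodes, ],
                            fit_ei <- kgfuse:::gat_edge_index(g), dropout = 0)
  expect_equal(unname(f1$embeddings$vectors), unname(kgfuse:::ad_value(Z)),
               tolerance = 1e-9)
})

test_that("link prediction covers every node and reproduces under a fixed seed", {
  g <- generate_ontology(ontology_spec(n_classes = 40L, n_top = 4L,
                                       seed = 10L))
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 3L)
  ft <- encode_node_features(g, enc)
  cfg <- gat_config(hidden_dim = 8L, embedding_dim = 8L, n_heads = 2L,
                    epochs = 10L, seed = 5L)
  f1 <- train_gat_link_prediction(g, ft, cfg)
  f2 <- train_gat_link_prediction(g, ft, cfg)
  expect_identical(f1$embeddings$vectors, f2$embeddings$vectors)
  expect_equal(f1$report$auc, f2$report$auc)
  expect_setequal(rownames(f1$embeddings$vectors), g$nodes)
  expect_equal(f1$embeddings$provenance, "link_prediction")
  small <- ontology_graph(list(list(id = "R", parents = character(0)),
                               list(id = "a", parents = "R")))
  expect_error(train_gat_link_prediction(
    small, encode_node_features(small, enc), cfg), "at least 10")
})

test_that("embedding tables serialize and reload losslessly", {
  g <- generate_ontology(ontology_spec(n_classes = 15L, n_top = 2L,
                                       seed = 12L))
  texts <- vapply(g$classes, assemble_node_text, character(1))
  enc <- new_tiny_encoder(wordpiece_vocab(texts), hidden = 8L, seed = 3L)
  fit <- train_gat_node_classification(
    g, encode_node_features(g, enc), assign_top_level_labels(g),
    gat_config(hidden_dim = 8L, embedding_dim = 8L, n_heads = 2L,
               epochs = 3L, seed = 2L))
  dir <- withr::local_tempdir()
  write_embeddings(fit$embeddings, dir)
  back <- read_embeddings(dir)
  expect_equal(back$vectors, fit$embeddings$vectors)
  expect_equal(back$provenance, fit$embeddings$provenance)
  expect_equal(back$dim, fit$embeddings$dim)
})

test_that("overlong node text is truncated with a warning", {
  enc <- new_tiny_encoder(wordpiece_vocab("w"), hidden = 8L, max_len = 8L,
                          seed = 1L)
  expect_warning(encode_words(enc, rep("w", 20L)), "truncated")
})
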