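# Shared fixtures and independent oracles. Everything is built in code;
# the oracles deliberately use different machinery (regexes, exhaustive
# loops, numerical differentiation) than the implementation they check.

toy_symptom_graph <- function() {
  ontology_graph(list(
    list(id = "SYMP:ROOT", label = "symptom", parents = character(0)),
    list(id = "SYMP:NP", label = "neurological and physiological symptom",
         parents = "SYMP:ROOT"),
    list(id = "SYMP:NS", label = "nervous system symptom",
         parents = "SYMP:ROOT"),
    list(id = "SYMP:DROW", label = "Drowsiness", synonyms = "drowsy",
         definition = "reduced wakefulness", parents = "SYMP:NP"),
    list(id = "SYMP:TIRE", label = "Tiredness", synonyms = "tired",
         parents = "SYMP:NP"),
    list(id = "SYMP:PAIN", label = "Pain", parents = "SYMP:NS")))
}

toy_drug_graph <- function() {
  ontology_graph(list(
    list(id = "DRUG:ROOT", label = "drug", parents = character(0)),
    list(id = "DRUG:NSAID", label = "nsaid", parents = "DRUG:ROOT"),
    list(id = "DRUG:STATIN", label = "statin", parents = "DRUG:ROOT"),
    list(id = "DRUG:DICLO", label = "Diclofenac", synonyms = "voltaren",
         parents = "DRUG:NSAID"),
    list(id = "DRUG:LIPI", label = "Lipitor", synonyms = "atorvastatin",
         parents = "DRUG:STATIN")))
}

fig1_tokens <- function() {
  c("Very", "drowsy", "and", "tired", "and", "no", "pain", "relief",
    "at", "all", ".")
}

# Regex oracle for IOB aggregation: orphan-I repair, then runs of B I*.
oracle_iob_spans <- function(labels) {
  s <- paste(labels, collapse = "")
  s <- gsub("(^|O)I", "\\1B", s)
  m <- gregexpr("BI*", s)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 2L)
}

# Exhaustive-loop oracle for strict counts.
oracle_strict_counts <- function(gold, pred) {
  eq <- function(a, i, b, j) {
    a$doc[i] == b$doc[j] && a$sent[i] == b$sent[j] &&
      a$start[i] == b$start[j] && a$end[i] == b$end[j]
  }
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (eq(pred, i, gold, j)) { tp <- tp + 1L; break }
    }
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

random_span_frame <- function(n, sent_len = 20L, n_sent = 2L) {
  if (n == 0L) {
    return(data.frame(doc = character(0), sent = integer(0),
                      start = integer(0), end = integer(0)))
  }
  start <- sample.int(sent_len, n, replace = TRUE) - 1L
  data.frame(doc = "d", sent = sample.int(n_sent, n, replace = TRUE),
             start = start,
             end = pmin(start + sample(0:3, n, replace = TRUE),
                        sent_len - 1L))
}

random_iob <- function(len) {
  sample(c("O", "B", "I"), len, replace = TRUE, prob = c(0.6, 0.2, 0.2))
}

# Central-difference gradient of a scalar-valued function of one matrix.
numeric_grad <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + eps
      Xm <- X; Xm[i, j] <- Xm[i, j] - eps
      G[i, j] <- (f(Xp) - f(Xm)) / (2 * eps)
    }
  }
  G
}

as_corpus_test <- function(docs) kgfuse:::as_corpus(docs)

# A small corpus + knowledge pair for fusion/training tests.
tiny_experiment_inputs <- function(seed = 7L, n_docs = 20L) {
  gd <- generate_ontology(ontology_spec(n_classes = 30L, n_top = 3L,
                                        prefix = "DRUG", seed = 31L))
  gs <- generate_ontology(ontology_spec(n_classes = 50L, n_top = 3L,
                                        seed = 32L))
  corpus <- generate_corpus(gd, gs, corpus_spec(n_docs = n_docs,
                                                sentences_per_doc = 3,
                                                seed = seed))
  list(g_drug = gd, g_symp = gs, corpus = corpus)
}
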