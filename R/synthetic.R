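# Synthetic ontologies and annotated corpora.
#
# The generators make every stage of the pipeline testable without any
# licensed corpus: tree-shaped ontologies with annotated classes and a fixed
# number of top-level branches, and document corpora whose ADE spans co-occur
# with lexicon entities at a controlled rate. The co-occurrence knob
# (`p_signal`) is what makes knowledge fusion falsifiable on synthetic data:
# an ADE span is, with that probability, a symptom-lexicon phrase sitting in
# the same sentence as a drug-lexicon mention, so the tagger fires on it and
# the fusion model receives its node embedding — including for surface forms
# never seen in training.

syllable_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v",
            "z", "br", "ch", "dr", "gl", "pl", "st", "tr")
  vow <- c("a", "e", "i", "o", "u", "ai", "ea", "ou")
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    ns <- sample(2:4, 2L * k, replace = TRUE)
    w <- vapply(ns, function(s) {
      paste0(paste0(sample(cons, s, replace = TRUE),
                    sample(vow, s, replace = TRUE)), collapse = "")
    }, character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Specification of a synthetic tree ontology
#'
#' @param n_classes Total classes including the root.
#' @param n_top Number of root children (top-level branches).
#' @param synonyms_per_class Synonyms per class.
#' @param vocab Word list labels and synonyms are drawn from without
#'   replacement; `NULL` generates a pseudo-word vocabulary of the required
#'   size.
#' @param multiword_frac Fraction of class labels made of two vocabulary
#'   words (multi-token surface forms).
#' @param prefix Identifier prefix (ids are `PREFIX:0000001`, ...).
#' @param seed Integer seed.
#' @return A list of class `ontology_spec`.
#' @export
ontology_spec <- function(n_classes, n_top = 14L, synonyms_per_class = 1L,
                          vocab = NULL, multiword_frac = 0.3,
                          prefix = "SYN", seed = 1L) {
  stopifnot(n_classes >= 1L, n_top >= 0L, n_top < n_classes,
            synonyms_per_class >= 0L)
  structure(list(n_classes = n_classes, n_top = n_top,
                 synonyms_per_class = synonyms_per_class, vocab = vocab,
                 multiword_frac = multiword_frac, prefix = prefix,
                 seed = seed),
            class = "ontology_spec")
}

#' Generate a random tree ontology
#'
#' A rooted tree with `n_classes` nodes whose root has exactly `n_top`
#' children; every class receives a label and `synonyms_per_class` synonyms
#' drawn without replacement from the vocabulary. Deterministic per seed.
#'
#' @param spec An [ontology_spec()].
#' @return An [ontology_graph()].
#' @export
generate_ontology <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_classes
  # Every class consumes at most 2 + synonyms_per_class words (two-word label).
  need <- n * (2L + spec$synonyms_per_class)
  vocab <- spec$vocab
  if (is.null(vocab)) vocab <- syllable_words(need)
  if (length(vocab) < need) {
    stop("vocab too small: need ", need, " words, have ", length(vocab))
  }
  vocab <- sample(vocab)
  ids <- sprintf("%s:%07d", spec$prefix, seq_len(n))
  parents <- rep(NA_character_, n)
  if (n > 1L) {
    top <- seq(2L, min(1L + spec$n_top, n))
    parents[top] <- ids[1]
    if (n > 1L + spec$n_top) {
      for (k in seq(2L + spec$n_top, n)) {
        parents[k] <- ids[sample(seq(2L, k - 1L), 1L)]
      }
    }
  }
  take <- local({
    i <- 0L
    function(k) { i <<- i + k; vocab[seq(i - k + 1L, i)] }
  })
  classes <- vector("list", n)
  for (k in seq_len(n)) {
    lab <- if (k > 1L && stats::runif(1) < spec$multiword_frac) {
      paste(take(2L), collapse = " ")
    } else take(1L)
    classes[[k]] <- list(
      id = ids[k], label = lab,
      synonyms = if (spec$synonyms_per_class)
        take(spec$synonyms_per_class) else character(0),
      definition = paste("a", lab, "finding"),
      parents = if (is.na(parents[k])) character(0) else parents[k])
  }
  ontology_graph(classes)
}

#' Specification of a synthetic annotated corpus
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Mean sentences per document (>= 1).
#' @param p_signal Probability that an ADE span's surface form is a
#'   symptom-lexicon phrase adjacent to a drug-lexicon mention.
#' @param p_background_ade Probability that a sentence carries an additional
#'   out-of-lexicon ADE phrase.
#' @param noise_rate Typo/casing perturbation probability per filler token.
#' @param symptom_overlap Fraction of ADE symptom draws taken from a small
#'   reused surface pool; the remaining draws each use a surface form at most
#'   once in the corpus, so roughly this fraction of test-split ADE surfaces
#'   also occurs in a training split.
#' @param n_filler_vocab Size of the filler-word vocabulary.
#' @param seed Integer seed.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 120L, sentences_per_doc = 4,
                        p_signal = 0.9, p_background_ade = 0.05,
                        noise_rate = 0.02, symptom_overlap = 0.5,
                        n_filler_vocab = 2000L, seed = 1L) {
  stopifnot(n_docs >= 1L, sentences_per_doc >= 1,
            p_signal >= 0, p_signal <= 1,
            p_background_ade >= 0, p_background_ade <= 1,
            noise_rate >= 0, noise_rate <= 1,
            symptom_overlap >= 0, symptom_overlap <= 1)
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 p_signal = p_signal, p_background_ade = p_background_ade,
                 noise_rate = noise_rate, symptom_overlap = symptom_overlap,
                 n_filler_vocab = n_filler_vocab, seed = seed),
            class = "corpus_spec")
}

perturb_token <- function(tok) {
  if (stats::runif(1) < 0.5) {
    # casing flip of the first character
    first <- substr(tok, 1L, 1L)
    paste0(if (first == toupper(first)) tolower(first) else toupper(first),
           substring(tok, 2L))
  } else {
    i <- sample(nchar(tok), 1L)
    paste0(substr(tok, 1L, i), substring(tok, i))
  }
}

#' Generate an annotated ADE corpus
#'
#' Template sentences interleave filler words, drug mentions (drug-lexicon
#' surface forms) and ADE spans. With probability `p_signal` an ADE span's
#' surface form is a symptom-lexicon phrase in the same sentence as a drug
#' mention; otherwise it is an out-of-lexicon phrase. Sentences may also
#' carry symptom mentions with no drug (not ADEs) or drug mentions with no
#' ADE, so neither cue alone determines the label. Gold spans are recorded at
#' the character level (annotation types `ADE`, plus `Drug` and `Symptom`
#' provenance); deterministic per seed.
#'
#' @param g_drug,g_symp Ontology graphs providing the drug and symptom
#'   lexicons.
#' @param spec A [corpus_spec()].
#' @return An `ade_corpus`.
#' @export
generate_corpus <- function(g_drug, g_symp, spec = corpus_spec()) {
  set.seed(spec$seed)
  lex_drug <- build_lexicon(g_drug, "drug")
  lex_symp <- build_lexicon(g_symp, "symptom")
  if (spec$p_signal > 0 && !length(lex_symp$entries)) {
    stop("impossible spec: p_signal > 0 with an empty symptom lexicon")
  }
  if (!length(lex_drug$entries)) stop("empty drug lexicon")
  symp_forms <- names(lex_symp$entries)
  drug_forms <- names(lex_drug$entries)
  # Reused-versus-once symptom surface pools controlling train/test overlap.
  n_common <- max(1L, min(round(0.1 * length(symp_forms)), 40L))
  common_pool <- sample(symp_forms, n_common)
  rare_pool <- sample(setdiff(symp_forms, common_pool))
  rare_next <- 0L
  draw_symptom <- function() {
    if (stats::runif(1) < spec$symptom_overlap || !length(rare_pool)) {
      sample(common_pool, 1L)
    } else {
      rare_next <<- rare_next + 1L
      if (rare_next > length(rare_pool)) {
        stop("capacity error: symptom lexicon too small for this corpus ",
             "at symptom_overlap = ", spec$symptom_overlap)
      }
      rare_pool[rare_next]
    }
  }
  filler <- syllable_words(spec$n_filler_vocab + 600L)
  filler <- filler[!filler %in% c(symp_forms, drug_forms)]
  n_bg <- min(300L, floor(length(filler) / 4L))
  background_vocab <- filler[seq_len(n_bg)]
  filler <- filler[-seq_len(n_bg)]
  fill <- function(k) sample(filler, k, replace = TRUE)
  docs <- vector("list", spec$n_docs)
  for (d in seq_len(spec$n_docs)) {
    n_sent <- 1L + stats::rpois(1L, max(spec$sentences_per_doc - 1, 0))
    sent_tokens <- vector("list", n_sent)
    sent_ann <- vector("list", n_sent)
    for (si in seq_len(n_sent)) {
      kind <- sample(c("ade", "symptom_only", "drug_only", "filler"), 1L,
                     prob = c(0.45, 0.2, 0.15, 0.2))
      toks <- character(0)
      ents <- list()   # list of (type, token index range)
      add <- function(words, type = NULL) {
        ix <- length(toks) + seq_along(words)
        toks <<- c(toks, words)
        if (!is.null(type)) {
          ents[[length(ents) + 1L]] <<- list(type = type, ix = range(ix))
        }
      }
      add(fill(sample(1:3, 1L)))
      if (kind %in% c("ade", "drug_only")) {
        drug <- strsplit(sample(drug_forms, 1L), " ", fixed = TRUE)[[1]]
        add(drug, "Drug")
        add(fill(sample(1:3, 1L)))
      }
      if (kind == "ade") {
        if (stats::runif(1) < spec$p_signal) {
          phrase <- strsplit(draw_symptom(), " ", fixed = TRUE)[[1]]
          add(phrase, "ADE+Symptom")
        } else {
          phrase <- sample(background_vocab, sample(1:2, 1L))
          add(phrase, "ADE")
        }
        add(fill(sample(1:2, 1L)))
      }
      if (kind == "symptom_only") {
        add(strsplit(draw_symptom(), " ", fixed = TRUE)[[1]], "Symptom")
        add(fill(sample(1:2, 1L)))
      }
      if (kind == "filler") add(fill(sample(2:5, 1L)))
      if (stats::runif(1) < spec$p_background_ade) {
        add(sample(background_vocab, sample(1:2, 1L)), "ADE")
        add(fill(1L))
      }
      # Typo/casing noise on non-entity tokens only.
      if (spec$noise_rate > 0) {
        ent_ix <- unlist(lapply(ents, function(e) seq(e$ix[1], e$ix[2])))
        for (t in setdiff(seq_along(toks), ent_ix)) {
          if (stats::runif(1) < spec$noise_rate) {
            toks[t] <- perturb_token(toks[t])
          }
        }
      }
      toks <- c(toks, ".")
      sent_tokens[[si]] <- toks
      sent_ann[[si]] <- ents
    }
    # Assemble text and character-level annotations.
    text_lines <- vapply(sent_tokens, paste, character(1), collapse = " ")
    text <- paste(text_lines, collapse = "\n")
    offs <- cumsum(c(0L, nchar(text_lines) + 1L))
    ann <- list()
    for (si in seq_len(n_sent)) {
      toks <- sent_tokens[[si]]
      starts <- offs[si] + c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
      ends <- starts + nchar(toks)
      for (e in sent_ann[[si]]) {
        st <- starts[e$ix[1]]; en <- ends[e$ix[2]]
        types <- strsplit(e$type, "+", fixed = TRUE)[[1]]
        for (ty in types) {
          ann[[length(ann) + 1L]] <- data.frame(
            start = st, end = en, type = ty,
            text = substr(text, st + 1L, en), stringsAsFactors = FALSE)
        }
      }
    }
    ann <- if (length(ann)) do.call(rbind, ann) else NULL
    if (!is.null(ann)) ann$id <- paste0("T", seq_len(nrow(ann)))
    docs[[d]] <- ade_document(sprintf("doc%04d", d), text, ann)
  }
  as_corpus(docs)
}
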