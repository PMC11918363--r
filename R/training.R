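# Experimental protocol: document-level splits (64/16/20), AdamW training of
# the IOB labeler with token-level cross-entropy (non-pivot wordpieces masked
# out of the loss), TPE-style Bayesian hyperparameter search maximizing
# validation strict F1, and a final retrain on train+validation.

#' Split specification
#'
#' @param test_frac Fraction reserved for the independent test set.
#' @param val_frac_of_rest Fraction of the remainder used for validation
#'   (0.2 of 0.8 = 4-to-1 train/validation).
#' @param seed Integer seed.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(test_frac = 0.2, val_frac_of_rest = 0.2, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac_of_rest > 0,
            val_frac_of_rest < 1)
  structure(list(test_frac = test_frac, val_frac_of_rest = val_frac_of_rest,
                 seed = seed), class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Document-level random split of a corpus
#'
#' Splitting at the document level (post/tweet/label/report), never at the
#' sentence level, so sentences of one document cannot leak across
#' partitions. Sizes: |test| = round(test_frac * n), then |val| =
#' round(val_frac_of_rest * (n - |test|)), rounding half up.
#'
#' @param corpus An `ade_corpus` (or any named list of documents).
#' @param spec A [split_spec()].
#' @return List with `train`, `val`, `test` subcorpora and `ids`.
#' @export
split_dataset <- function(corpus, spec = split_spec()) {
  n <- length(corpus)
  if (n < 5L) stop("too few documents to split: ", n)
  set.seed(spec$seed)
  ids <- names(corpus)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  perm <- sample(ids)
  n_test <- round_half_up(spec$test_frac * n)
  n_val <- round_half_up(spec$val_frac_of_rest * (n - n_test))
  test_ids <- perm[seq_len(n_test)]
  val_ids <- perm[n_test + seq_len(n_val)]
  train_ids <- perm[-seq_len(n_test + n_val)]
  list(train = corpus[sort(match(train_ids, ids))],
       val = corpus[sort(match(val_ids, ids))],
       test = corpus[sort(match(test_ids, ids))],
       ids = list(train = train_ids, val = val_ids, test = test_ids))
}

#' NER training hyperparameters
#'
#' @param learning_rate AdamW step size.
#' @param batch_size Sentences per optimizer step (gradient accumulation).
#' @param epochs Passes over the training sentences.
#' @param weight_decay Decoupled weight decay.
#' @param head_dropout Dropout before the linear head.
#' @param warmup_frac Fraction of total steps with linear learning-rate
#'   warmup.
#' @return List of class `hyperparameters`.
#' @export
hyperparameters <- function(learning_rate = 3e-3, batch_size = 8L,
                            epochs = 6L, weight_decay = 0.01,
                            head_dropout = 0.1, warmup_frac = 0.1) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, epochs >= 0L,
            weight_decay >= 0, head_dropout >= 0, head_dropout < 1,
            warmup_frac >= 0, warmup_frac <= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, weight_decay = weight_decay,
                 head_dropout = head_dropout, warmup_frac = warmup_frac),
            class = "hyperparameters")
}

corpus_sentences_iob <- function(corpus) {
  iob <- corpus_to_iob(corpus, tagset = "plain")
  out <- list()
  for (d in iob) {
    for (s in d$sentences) {
      if (length(s$tokens)) {
        out[[length(out) + 1L]] <- list(doc = d$id, words = s$tokens,
                                        labels = s$labels)
      }
    }
  }
  out
}

#' Train an IOB sequence labeler
#'
#' Minimizes token-level cross-entropy (masked wordpieces carry no loss) with
#' AdamW and linear warmup; validation strict span F1 is computed after every
#' epoch and the best-on-validation parameters are restored at the end.
#' Identical seeds give identical histories.
#'
#' @param model A [new_ner_model()].
#' @param train,val `ade_corpus` partitions; `val = NULL` skips monitoring
#'   and keeps the last epoch's parameters.
#' @param hp A [hyperparameters()].
#' @param seed Integer seed for shuffling, dropout and negative sampling.
#' @return The trained `kgfuse_ner`, with `history` (per-epoch `train_loss`,
#'   `val_f1`) and `best_epoch` attached.
#' @export
train_ner <- function(model, train, val, hp = hyperparameters(), seed = 1L) {
  sents <- corpus_sentences_iob(train)
  if (!length(sents)) stop("empty training set")
  model$head_dropout <- hp$head_dropout
  preps <- lapply(sents, function(s) {
    prepare_sentence(model, s$words, s$labels)
  })
  # For the fixed variant the GNN is outside the trainable set entirely: its
  # embeddings enter as constants, so no gradient can reach it.
  params <- ner_trainable_params(model)
  opt <- adamw_init(params)
  total_steps <- max(1L, hp$epochs * ceiling(length(preps) / hp$batch_size))
  warm <- max(1, round(hp$warmup_frac * total_steps))
  step <- 0L
  set.seed(seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_f1 = numeric(0))
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  gold_val <- if (!is.null(val)) gold_spans(val)
  for (ep in seq_len(hp$epochs)) {
    ord <- sample(seq_along(preps))
    ep_loss <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
      tp <- ad_tape()
      pnodes <- params_to_leaves(tp, params)
      Z <- if (model$variant == "adaptive")
        adaptive_graph_node(tp, model, pnodes)
      losses <- lapply(b, function(i) {
        ner_sentence_logits(tp, model, pnodes, preps[[i]], Z, train = TRUE)
      })
      loss <- NULL
      for (i in seq_along(b)) {
        l <- ad_softmax_xent(losses[[i]], preps[[b[i]]]$target)
        loss <- if (is.null(loss)) l else ad_add(loss, l)
      }
      loss <- ad_scale(loss, 1 / length(b))
      ad_backward(loss)
      ep_loss <- ep_loss + ad_value(loss); nb <- nb + 1L
      grads <- lapply(pnodes, ad_grad)
      step <- step + 1L
      lr <- hp$learning_rate * min(1, step / warm)
      st <- adamw_step(params, grads, opt, lr = lr,
                       weight_decay = hp$weight_decay,
                       no_decay = grep("(_b[0-9]?$|_ln|^bh$|lnf_)",
                                       names(params), value = TRUE))
      params <- st$params; opt <- st$state
    }
    f1 <- NA_real_
    if (!is.null(val)) {
      m2 <- ner_write_back(model, params)
      f1 <- evaluate_ner(m2, val, gold = gold_val)$f1
      if (f1 > best$f1) best <- list(f1 = f1, params = params, epoch = ep)
    } else {
      best <- list(f1 = NA_real_, params = params, epoch = ep)
    }
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / nb,
                                val_f1 = f1))
  }
  model <- ner_write_back(model, best$params)
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' @export
summary.kgfuse_ner <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) print(object$history)
  invisible(object)
}

#' Evaluate a labeler on a corpus
#'
#' @param model A trained `kgfuse_ner`.
#' @param corpus An `ade_corpus` with gold ADE annotations.
#' @param mode `"strict"` or `"relaxed"`.
#' @param gold Optional precomputed gold span frame.
#' @return An `eval_report`.
#' @export
evaluate_ner <- function(model, corpus, mode = c("strict", "relaxed"),
                         gold = NULL) {
  mode <- match.arg(mode)
  if (is.null(gold)) gold <- gold_spans(corpus)
  pred <- predict(model, corpus)$spans
  if (mode == "strict") strict_prf(gold, pred) else relaxed_prf(gold, pred)
}

sample_param <- function(def) {
  switch(def$type,
         loguniform = exp(stats::runif(1, log(def$low), log(def$high))),
         uniform = stats::runif(1, def$low, def$high),
         int = sample(seq(def$low, def$high), 1L),
         choice = def$values[[sample(length(def$values), 1L)]],
         stop("config error: unknown parameter type ", def$type))
}

# Density-ratio scoring of one candidate value under the TPE split.
tpe_score <- function(x, good, bad, def) {
  if (def$type == "choice") {
    vals <- vapply(def$values, identical, logical(1), x)
    gi <- which(vals)
    lg <- (sum(vapply(good, identical, logical(1), x)) + 1) /
      (length(good) + length(def$values))
    lb <- (sum(vapply(bad, identical, logical(1), x)) + 1) /
      (length(bad) + length(def$values))
    return(lg / lb)
  }
  tr <- function(v) if (def$type == "loguniform") log(as.numeric(v))
                    else as.numeric(v)
  span <- tr(def$high) - tr(def$low)
  bw <- max(span / 5, 1e-9)
  kde <- function(obs) {
    if (!length(obs)) return(1 / span)
    mean(stats::dnorm(tr(x), mean = vapply(obs, tr, numeric(1)), sd = bw)) +
      1e-12
  }
  kde(good) / kde(bad)
}

#' TPE-style sequential hyperparameter search
#'
#' Sequential model-based optimization in the tree-structured Parzen
#' estimator style: after a few random startup trials, completed trials are
#' split by an objective quantile into good and bad sets, candidates are
#' drawn from the prior, and the candidate maximizing the good/bad density
#' ratio (per parameter, independently) is evaluated next. Maximizes the
#' objective; deterministic per seed.
#'
#' @param objective Function taking a named hyperparameter list, returning a
#'   numeric score (e.g. validation strict F1).
#' @param space Named list of parameter definitions, each a list with
#'   `type` (`"loguniform"`, `"uniform"`, `"int"`, `"choice"`) and
#'   `low`/`high` or `values`.
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed.
#' @param n_startup Random trials before the model kicks in.
#' @param gamma Quantile defining the good set.
#' @return List with `best` (hyperparameter list), `best_value`, and
#'   `trials` (full log: parameters and objective per trial).
#' @export
tune_hyperparameters <- function(objective, space = default_search_space(),
                                 budget = 20L, seed = 1L, n_startup = 5L,
                                 gamma = 1 / 3) {
  stopifnot(budget >= 1L)
  for (def in space) {
    if (!is.null(def$low) && !is.null(def$high) && def$low > def$high) {
      stop("config error: search space has low > high")
    }
  }
  set.seed(seed)
  trials <- list()
  for (t in seq_len(budget)) {
    if (t <= n_startup || t <= 2L) {
      hp <- lapply(space, sample_param)
    } else {
      vals <- vapply(trials, `[[`, numeric(1), "value")
      cut <- stats::quantile(vals, 1 - gamma, names = FALSE)
      good_ix <- which(vals >= cut)
      bad_ix <- setdiff(seq_along(vals), good_ix)
      hp <- list()
      for (nm in names(space)) {
        good <- lapply(trials[good_ix], function(x) x$hp[[nm]])
        bad <- lapply(trials[bad_ix], function(x) x$hp[[nm]])
        cands <- lapply(seq_len(24L), function(i) sample_param(space[[nm]]))
        sc <- vapply(cands, tpe_score, numeric(1), good, bad, space[[nm]])
        hp[[nm]] <- cands[[which.max(sc)]]
      }
    }
    trials[[t]] <- list(hp = hp, value = objective(hp))
  }
  vals <- vapply(trials, `[[`, numeric(1), "value")
  best <- trials[[which.max(vals)]]
  list(best = best$hp, best_value = best$value, trials = trials)
}

#' Default NER search space
#'
#' @return A named list usable as `space` in [tune_hyperparameters()].
#' @export
default_search_space <- function() {
  list(learning_rate = list(type = "loguniform", low = 1e-5, high = 1e-4),
       batch_size = list(type = "choice", values = list(8L, 16L, 32L)),
       epochs = list(type = "int", low = 2L, high = 10L),
       weight_decay = list(type = "uniform", low = 0, high = 0.1),
       head_dropout = list(type = "uniform", low = 0, high = 0.3))
}

#' Final retrain on train + validation
#'
#' Rebuilds the model from scratch via `model_factory` and trains it on the
#' union of the training and validation documents with the tuned
#' hyperparameters. The test partition must stay untouched: any overlap with
#' it raises a leakage error.
#'
#' @param model_factory Function `(seed) -> kgfuse_ner` returning a freshly
#'   initialized model.
#' @param train,val `ade_corpus` partitions (disjoint).
#' @param best_hp A [hyperparameters()] list.
#' @param seed Integer seed.
#' @param test Optional test partition used only for the leakage check.
#' @return The retrained `kgfuse_ner`.
#' @export
final_fit <- function(model_factory, train, val, best_hp, seed = 1L,
                      test = NULL) {
  if (length(intersect(names(train), names(val)))) {
    stop("leakage error: train and validation sets overlap")
  }
  if (!is.null(test) &&
      length(intersect(c(names(train), names(val)), names(test)))) {
    stop("leakage error: test document found in train/validation")
  }
  fused <- as_corpus(c(unclass(train), unclass(val)))
  model <- model_factory(seed)
  if (best_hp$epochs == 0L) return(model)
  # Retrain from scratch on train + validation for the tuned number of
  # epochs; no validation monitoring, the test set stays untouched.
  train_ner(model, fused, val = NULL, hp = best_hp, seed = seed)
}
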