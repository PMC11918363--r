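# Rule-based lexicon tagger.
#
# Drug and symptom mentions are found by dictionary lookup against the
# knowledge graph's labels and synonyms (brand names included). A rule-based
# matcher is used deliberately — it keeps false-positive knowledge injection
# low — so normalization is conservative: lowercasing, surrounding-punctuation
# stripping and whitespace collapsing only, no stemming.

normalize_surface <- function(x) {
  x <- tolower(x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x <- gsub("\\s+", " ", trimws(x))
  x
}

#' Build a lexicon from an ontology graph
#'
#' One entry per distinct normalized label/synonym surface form, mapping to
#' the owning node. When two classes share a surface form the entry goes to
#' the shallower node (closer to the root), with ties broken by the
#' lexicographically smaller node id; collisions are reported via a warning.
#'
#' @param g An `ontology_graph`.
#' @param source One of `"drug"`, `"symptom"`, `"combined"`; a semantic tag
#'   carried into tagged spans.
#' @param include_root Include the root class's own annotations (default
#'   FALSE; roots are structural).
#' @return Object of class `kg_lexicon`: list with `entries` (named character
#'   vector surface -> node id), `src` (surface -> source tag), `max_len`
#'   (longest entry in tokens) and `source`.
#' @export
build_lexicon <- function(g, source = c("drug", "symptom", "combined"),
                          include_root = FALSE) {
  source <- match.arg(source)
  depths <- node_depths(g)
  surfaces <- character(0); owners <- character(0)
  ids <- if (include_root) g$nodes else setdiff(g$nodes, g$root)
  for (id in ids) {
    cls <- g$classes[[id]]
    forms <- c(cls$label, cls$synonyms)
    forms <- forms[nzchar(forms)]
    if (!length(forms)) forms <- cls$id
    forms <- unique(normalize_surface(forms))
    forms <- forms[nzchar(forms)]
    surfaces <- c(surfaces, forms)
    owners <- c(owners, rep(id, length(forms)))
  }
  if (!length(surfaces)) {
    warning("empty ontology annotations: lexicon has no entries")
    return(structure(list(entries = character(0), src = character(0),
                          max_len = 0L, source = source),
                     class = "kg_lexicon"))
  }
  # Deterministic collision resolution: shallower node, then smaller id.
  ord <- order(surfaces, depths[owners], owners, method = "radix")
  surfaces <- surfaces[ord]; owners <- owners[ord]
  dup <- duplicated(surfaces)
  if (any(dup)) {
    warning(sum(dup), " colliding surface form(s) resolved to the ",
            "shallowest node, e.g. '", surfaces[dup][1], "'")
  }
  entries <- structure(owners[!dup], names = surfaces[!dup])
  structure(list(entries = entries,
                 src = structure(rep(source, length(entries)),
                                 names = names(entries)),
                 max_len = max(lengths(strsplit(names(entries), " ",
                                                fixed = TRUE))),
                 source = source),
            class = "kg_lexicon")
}

#' Merge two lexicons
#'
#' Surface forms present in both keep the drug entry when sources differ
#' (drug beats symptom), otherwise the lexicographically smaller node id.
#'
#' @param a,b `kg_lexicon` objects.
#' @return A combined `kg_lexicon` with `source = "combined"`.
#' @export
merge_lexicons <- function(a, b) {
  surfaces <- c(names(a$entries), names(b$entries))
  owners <- c(unname(a$entries), unname(b$entries))
  srcs <- c(unname(a$src), unname(b$src))
  pri <- ifelse(srcs == "drug", 0L, 1L)
  ord <- order(surfaces, pri, owners, method = "radix")
  surfaces <- surfaces[ord]; owners <- owners[ord]; srcs <- srcs[ord]
  keep <- !duplicated(surfaces)
  structure(list(entries = structure(owners[keep], names = surfaces[keep]),
                 src = structure(srcs[keep], names = surfaces[keep]),
                 max_len = max(a$max_len, b$max_len),
                 source = "combined"),
            class = "kg_lexicon")
}

#' @export
print.kg_lexicon <- function(x, ...) {
  cat(sprintf("kg_lexicon (%s): %d entries, max length %d tokens\n",
              x$source, length(x$entries), x$max_len))
  invisible(x)
}

#' Tag entity mentions in a token sequence
#'
#' Greedy left-to-right longest match of token n-grams (up to the lexicon's
#' longest entry) against the lexicon, case-insensitive; matched spans carry
#' the lexicon node id and source. Spans never overlap.
#'
#' @param tokens Character vector of word tokens.
#' @param lex A `kg_lexicon`.
#' @return Object of class `tagged_sequence`: list with `tokens` and `spans`
#'   (data frame with 0-based inclusive `start`, `end`, plus `node`,
#'   `source`).
#' @export
tag <- function(tokens, lex) {
  stopifnot(length(tokens) > 0L)
  norm <- normalize_surface(tokens)
  n <- length(tokens)
  spans <- list()
  # Resolve all candidate n-grams in one match() call, then scan greedily.
  hit <- NULL
  if (length(lex$entries)) {
    cand_i <- integer(0); cand_l <- integer(0); keys <- character(0)
    for (i in seq_len(n)) {
      for (l in seq_len(min(lex$max_len, n - i + 1L))) {
        cand_i <- c(cand_i, i); cand_l <- c(cand_l, l)
        keys <- c(keys, gsub("\\s+", " ",
                             trimws(paste(norm[i:(i + l - 1L)],
                                          collapse = " "))))
      }
    }
    m <- match(keys, names(lex$entries))
    hit <- structure(m, names = paste(cand_i, cand_l))
  }
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    if (!is.null(hit)) {
      for (l in seq(min(lex$max_len, n - i + 1L), 1L)) {
        e <- hit[[paste(i, l)]]
        if (!is.na(e)) {
          spans[[length(spans) + 1L]] <-
            list(start = i - 1L, end = i + l - 2L,
                 node = unname(lex$entries[[e]]),
                 source = unname(lex$src[[e]]))
          hit_len <- l
          break
        }
      }
    }
    i <- i + max(hit_len, 1L)
  }
  spans <- if (length(spans)) {
    data.frame(start = vapply(spans, `[[`, integer(1), "start"),
               end = vapply(spans, `[[`, integer(1), "end"),
               node = vapply(spans, `[[`, character(1), "node"),
               source = vapply(spans, `[[`, character(1), "source"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = integer(0), end = integer(0), node = character(0),
               source = character(0), stringsAsFactors = FALSE)
  }
  structure(list(tokens = tokens, spans = spans), class = "tagged_sequence")
}

#' @export
print.tagged_sequence <- function(x, ...) {
  cat(sprintf("tagged_sequence: %d tokens, %d spans\n",
              length(x$tokens), nrow(x$spans)))
  invisible(x)
}

#' Write / read a lexicon as TSV
#'
#' Columns: surface form, node id, source.
#' @param lex A `kg_lexicon`.
#' @param path File path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` the
#'   reloaded lexicon.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(names(lex$entries), unname(lex$entries), unname(lex$src),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surfaces <- vapply(parts, `[`, character(1), 1L)
  src <- vapply(parts, `[`, character(1), 3L)
  structure(list(entries = structure(vapply(parts, `[`, character(1), 2L),
                                     names = surfaces),
                 src = structure(src, names = surfaces),
                 max_len = if (length(surfaces))
                   max(lengths(strsplit(surfaces, " ", fixed = TRUE))) else 0L,
                 source = if (length(unique(src)) == 1L) unique(src)
                          else "combined"),
            class = "kg_lexicon")
}
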