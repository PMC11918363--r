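# Readers and writers for the annotation formats ADE corpora ship in:
# brat standoff (.txt + .ann, character offsets, CADEC/PsyTAR style),
# CoNLL-style IOB (token TAB label), and a JSONL span format. Documents keep
# their raw text, a sentence/token segmentation with character offsets, and
# character-level annotations; token-level spans are derived by projection.
#
# Character offsets are 0-based with exclusive ends (brat convention); token
# indices are 0-based inclusive.

# Rule-based word tokenizer with offsets: alphanumeric runs (with internal
# apostrophes) or single punctuation marks.
word_tokenize <- function(text) {
  m <- gregexpr("[A-Za-z0-9_]+(?:'[A-Za-z0-9_]+)*|[^A-Za-z0-9_\\s]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(0), starts = integer(0),
                ends = integer(0)))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  list(tokens = substring(text, starts + 1L, starts + lens),
       starts = starts, ends = starts + lens)
}

#' Construct an annotated document
#'
#' Sentences are the newline-separated lines of `text`; each sentence is
#' word-tokenized with character offsets into the full text.
#'
#' @param id Document identifier.
#' @param text Raw text; newline separates sentences.
#' @param annotations Data frame with columns `start`, `end` (0-based,
#'   end-exclusive character offsets), `type`, `text`; may have an `id`
#'   column. Annotation text must equal the corresponding text slice.
#' @return Object of class `ade_document`.
#' @export
ade_document <- function(id, text, annotations = NULL) {
  if (is.null(annotations) || !nrow(annotations)) {
    annotations <- data.frame(id = character(0), start = integer(0),
                              end = integer(0), type = character(0),
                              text = character(0), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations)
    if (is.null(annotations$id)) {
      annotations$id <- paste0("T", seq_len(nrow(annotations)))
    }
    for (i in seq_len(nrow(annotations))) {
      slice <- substr(text, annotations$start[i] + 1L, annotations$end[i])
      if (!identical(slice, annotations$text[i])) {
        stop("annotation ", annotations$id[i],
             " does not match its text slice: '", slice, "' vs '",
             annotations$text[i], "'")
      }
    }
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  off <- 0L
  sentences <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    tk <- word_tokenize(lines[k])
    sentences[[k]] <- list(tokens = tk$tokens, starts = tk$starts + off,
                           ends = tk$ends + off)
    off <- off + nchar(lines[k]) + 1L
  }
  structure(list(id = id, text = text, sentences = sentences,
                 annotations = annotations[c("id", "start", "end", "type",
                                             "text")]),
            class = "ade_document")
}

#' @export
print.ade_document <- function(x, ...) {
  cat(sprintf("ade_document '%s': %d sentences, %d annotations\n",
              x$id, length(x$sentences), nrow(x$annotations)))
  invisible(x)
}

as_corpus <- function(docs) {
  names(docs) <- vapply(docs, `[[`, character(1), "id")
  structure(docs, class = "ade_corpus")
}

#' @export
print.ade_corpus <- function(x, ...) {
  ns <- sum(vapply(x, function(d) length(d$sentences), integer(1)))
  na <- sum(vapply(x, function(d) nrow(d$annotations), integer(1)))
  cat(sprintf("ade_corpus: %d documents, %d sentences, %d annotations\n",
              length(x), ns, na))
  invisible(x)
}

#' @export
`[.ade_corpus` <- function(x, i) as_corpus(unclass(x)[i])

#' Read a brat standoff document
#'
#' Parses entity (`T`) lines — id, type, character offsets (including
#' discontinuous `start end;start end` fragments) and surface text — and
#' verifies each surface string against its offsets. Discontinuous
#' annotations are collapsed to their covering range by default.
#'
#' @param txt_path,ann_path Parallel `.txt` / `.ann` files.
#' @param discontinuous `"cover"` (default) collapses fragments to the
#'   covering range; `"drop"` discards discontinuous annotations.
#' @return An [ade_document()]; its id is the `.txt` basename.
#' @export
read_brat <- function(txt_path, ann_path,
                      discontinuous = c("cover", "drop")) {
  discontinuous <- match.arg(discontinuous)
  text <- paste(sub("\r$", "", readLines(txt_path, warn = FALSE)),
                collapse = "\n")
  lines <- sub("\r$", "", readLines(ann_path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  ann <- list()
  for (ln in lines[startsWith(lines, "T")]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed brat line: ", ln)
    aid <- parts[1]
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    type <- mid[1]
    frag <- strsplit(paste(mid[-1], collapse = " "), ";", fixed = TRUE)[[1]]
    offs <- do.call(rbind, lapply(strsplit(trimws(frag), " "), as.integer))
    surface <- parts[3]
    # Verify: fragment slices joined by single spaces must equal the surface.
    got <- paste(substring(text, offs[, 1] + 1L, offs[, 2]), collapse = " ")
    if (gsub("\\s+", " ", got) != gsub("\\s+", " ", surface)) {
      stop("integrity error in annotation ", aid, ": offsets give '", got,
           "' but text field is '", surface, "'")
    }
    if (nrow(offs) > 1L && discontinuous == "drop") next
    st <- min(offs[, 1]); en <- max(offs[, 2])
    ann[[length(ann) + 1L]] <- data.frame(
      id = aid, start = st, end = en, type = type,
      text = substr(text, st + 1L, en), stringsAsFactors = FALSE)
  }
  ade_document(sub("\\.txt$", "", basename(txt_path)), text,
               if (length(ann)) do.call(rbind, ann) else NULL)
}

#' Write a corpus as brat standoff files
#'
#' @param corpus An `ade_corpus`.
#' @param dir Output directory (one `.txt`/`.ann` pair per document).
#' @return `dir`, invisibly.
#' @export
write_brat <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    writeLines(strsplit(doc$text, "\n", fixed = TRUE)[[1]],
               file.path(dir, paste0(doc$id, ".txt")))
    a <- doc$annotations
    lines <- if (nrow(a)) {
      paste0(a$id, "\t", a$type, " ", a$start, " ", a$end, "\t", a$text)
    } else character(0)
    writeLines(lines, file.path(dir, paste0(doc$id, ".ann")))
  }
  invisible(dir)
}

#' Read / write CoNLL-style IOB files
#'
#' Token TAB label lines, blank line between sentences, and a `# doc <id>`
#' line opening each document. Labels must be `O` or `B-X`/`I-X`. CRLF input
#' is accepted and normalized on write; read-write-read is a fixed point.
#'
#' @param path File path.
#' @return A list of documents, each a list with `id` and `sentences` (each
#'   with `tokens` and `labels`), of class `conll_corpus`.
#' @export
read_conll_iob <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  docs <- list(); cur_doc <- NULL; cur_tok <- character(0)
  cur_lab <- character(0); sentences <- list()
  flush_sent <- function() {
    if (length(cur_tok)) {
      sentences[[length(sentences) + 1L]] <<- list(tokens = cur_tok,
                                                   labels = cur_lab)
    }
    cur_tok <<- character(0); cur_lab <<- character(0)
  }
  flush_doc <- function() {
    flush_sent()
    if (!is.null(cur_doc)) {
      docs[[length(docs) + 1L]] <<- list(id = cur_doc, sentences = sentences)
    }
    sentences <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "# doc ")) {
      flush_doc()
      cur_doc <- substring(ln, 7L)
    } else if (!nzchar(ln)) {
      flush_sent()
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L ||
          !grepl("^(O|[BI]-[A-Za-z0-9_]+)$", parts[2])) {
        stop("format error at line ", i, " of ", path, ": '", ln, "'")
      }
      if (is.null(cur_doc)) cur_doc <- "doc1"
      cur_tok <- c(cur_tok, parts[1]); cur_lab <- c(cur_lab, parts[2])
    }
  }
  flush_doc()
  if (!length(docs)) warning("blank CoNLL file: ", path)
  structure(docs, class = "conll_corpus")
}

#' @rdname read_conll_iob
#' @param docs A `conll_corpus` (or compatible list).
#' @export
write_conll_iob <- function(docs, path) {
  out <- character(0)
  for (d in docs) {
    out <- c(out, paste0("# doc ", d$id))
    for (s in d$sentences) {
      out <- c(out, paste(s$tokens, s$labels, sep = "\t"), "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write a JSONL span corpus
#'
#' One document per line: `id`, `text`, and `spans` with character `start`,
#' `end` (0-based, end-exclusive), `type` and `text`.
#'
#' @param path File path.
#' @return An `ade_corpus`.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  as_corpus(lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    ann <- x$spans
    if (is.null(ann) || !length(ann)) ann <- NULL
    ade_document(x$id, x$text, ann)
  }))
}

#' @rdname read_jsonl
#' @param corpus An `ade_corpus`.
#' @export
write_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    jsonlite::toJSON(list(id = doc$id, text = doc$text,
                          spans = doc$annotations[c("start", "end", "type",
                                                    "text")]),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Project character-offset annotations to token spans
#'
#' Each character span maps to the minimal covering token range of its
#' sentence; partial token overlap rounds outward to whole tokens, and spans
#' crossing sentence boundaries are split per sentence.
#'
#' @param doc An `ade_document`.
#' @param types Annotation types to project (default all).
#' @return Data frame with `doc`, `sent` (1-based), `start`, `end` (0-based
#'   inclusive token indices) and `type`.
#' @export
project_char_spans <- function(doc, types = NULL) {
  a <- doc$annotations
  if (!is.null(types)) a <- a[a$type %in% types, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(a))) {
    if (a$end[i] <= a$start[i]) stop("zero-length span: ", a$id[i])
    if (a$start[i] < 0L || a$end[i] > nchar(doc$text)) {
      stop("span outside text: ", a$id[i])
    }
    for (k in seq_along(doc$sentences)) {
      s <- doc$sentences[[k]]
      hit <- which(s$starts < a$end[i] & s$ends > a$start[i])
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          doc = doc$id, sent = k, start = min(hit) - 1L,
          end = max(hit) - 1L, type = a$type[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(doc = character(0), sent = integer(0),
                      start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Gold ADE token spans of a corpus
#'
#' @param corpus An `ade_corpus`.
#' @param type Annotation type used as the NER target (default `"ADE"`).
#' @return Data frame of token spans (`doc`, `sent`, `start`, `end`).
#' @export
gold_spans <- function(corpus, type = "ADE") {
  out <- lapply(corpus, project_char_spans, types = type)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("doc", "sent", "start", "end")]
}

# Back-projection of a token span to character offsets (used in tests to
# check the projection always contains the original characters).
token_span_to_chars <- function(doc, sent, start, end) {
  s <- doc$sentences[[sent]]
  c(s$starts[start + 1L], s$ends[end + 1L])
}

#' Convert an annotated corpus to per-token IOB documents
#'
#' Uses only the given annotation type as the positive class.
#'
#' @param corpus An `ade_corpus`.
#' @param type Target annotation type (default `"ADE"`).
#' @param tagset `"plain"` for labels `O/B/I`, `"typed"` for `O/B-<type>/
#'   I-<type>`.
#' @return A `conll_corpus`-shaped list.
#' @export
corpus_to_iob <- function(corpus, type = "ADE",
                          tagset = c("typed", "plain")) {
  tagset <- match.arg(tagset)
  docs <- lapply(corpus, function(doc) {
    sp <- project_char_spans(doc, types = type)
    sentences <- lapply(seq_along(doc$sentences), function(k) {
      s <- doc$sentences[[k]]
      lab <- spans_to_iob(sp[sp$sent == k, , drop = FALSE],
                          length(s$tokens))
      if (tagset == "typed") {
        lab[lab == "B"] <- paste0("B-", type)
        lab[lab == "I"] <- paste0("I-", type)
      }
      list(tokens = s$tokens, labels = lab)
    })
    list(id = doc$id, sentences = sentences)
  })
  structure(unname(docs), class = "conll_corpus")
}
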