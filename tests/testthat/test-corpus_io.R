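test_that("brat annotations parse with verified offsets", {
  dir <- withr::local_tempdir()
  writeLines(c("Very drowsy and tired .", "second line here ."),
             file.path(dir, "d1.txt"))
  writeLines(c("T1\tADE 5 11\tdrowsy",
               "T2\tADE 0 4;16 21\tVery tired"),
             file.path(dir, "d1.ann"))
  doc <- read_brat(file.path(dir, "d1.txt"), file.path(dir, "d1.ann"))
  expect_equal(nrow(doc$annotations), 2L)
  expect_equal(doc$annotations$text[1], "drowsy")
  # discontinuous fragments collapse to the covering range by default
  expect_equal(doc$annotations$start[2], 0L)
  expect_equal(doc$annotations$end[2], 21L)
  doc2 <- read_brat(file.path(dir, "d1.txt"), file.path(dir, "d1.ann"),
                    discontinuous = "drop")
  expect_equal(nrow(doc2$annotations), 1L)
  # broken offsets raise an integrity error naming the annotation
  writeLines("T9\tADE 0 4\twrong", file.path(dir, "bad.ann"))
  expect_error(read_brat(file.path(dir, "d1.txt"),
                         file.path(dir, "bad.ann")), "T9")
  # empty .ann
  writeLines(character(0), file.path(dir, "empty.ann"))
  expect_equal(nrow(read_brat(file.path(dir, "d1.txt"),
                              file.path(dir, "empty.ann"))$annotations), 0L)
})

test_that("CoNLL IOB round-trips byte-identically and validates labels", {
  path <- withr::local_tempfile(fileext = ".conll")
  docs <- list(list(id = "a", sentences = list(
    list(tokens = c("Very", "drowsy", "."),
         labels = c("O", "B-ADE", "O")),
    list(tokens = c("ok", "now"), labels = c("O", "O")))))
  write_conll_iob(docs, path)
  back <- read_conll_iob(path)
  expect_equal(length(back), 1L)
  expect_equal(back[[1]]$sentences[[1]]$labels, c("O", "B-ADE", "O"))
  path2 <- withr::local_tempfile(fileext = ".conll")
  write_conll_iob(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  # CRLF input is accepted and normalized on write
  crlf <- withr::local_tempfile(fileext = ".conll")
  writeBin(charToRaw(gsub("\n", "\r\n", paste0(
    paste(readLines(path), collapse = "\n"), "\n"))), crlf)
  expect_equal(read_conll_iob(crlf), back)
  # unknown labels fail with a line number
  bad <- withr::local_tempfile(lines = c("# doc x", "tok\tB-"))
  expect_error(read_conll_iob(bad), "line 2")
  blank <- withr::local_tempfile(lines = character(0))
  expect_warning(read_conll_iob(blank), "blank")
})

test_that("JSONL corpora round-trip", {
  inp <- tiny_experiment_inputs(seed = 8L, n_docs = 5L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(inp$corpus, path)
  back <- read_jsonl(path)
  expect_equal(length(back), length(inp$corpus))
  for (id in names(inp$corpus)) {
    expect_equal(back[[id]]$text, inp$corpus[[id]]$text)
    expect_equal(back[[id]]$annotations[c("start", "end", "type", "text")],
                 inp$corpus[[id]]$annotations[c("start", "end", "type",
                                                "text")])
  }
  # write(read(x)) is a fixed point
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("character spans project outward to whole-token ranges", {
  doc <- ade_document("d", "Very drowsy and tired .",
                      data.frame(start = 5L, end = 11L, type = "ADE",
                                 text = "drowsy"))
  sp <- project_char_spans(doc)
  expect_equal(sp$start, 1L)
  expect_equal(sp$end, 1L)
  # half-token overlap rounds outward
  doc2 <- ade_document("d", "Very drowsy and tired .",
                       data.frame(start = 5L, end = 8L, type = "ADE",
                                  text = "dro"))
  sp2 <- project_char_spans(doc2)
  expect_equal(c(sp2$start, sp2$end), c(1L, 1L))
  # zero-length and out-of-bounds spans are rejected
  doc$annotations$end[1] <- doc$annotations$start[1]
  expect_error(project_char_spans(doc), "zero-length")
})

test_that("projection splits sentence-crossing spans and contains the original", {
  text <- "one two three\nfour five ."
  doc <- ade_document("d", text,
                      data.frame(start = 8L, end = 22L, type = "ADE",
                                 text = substr(text, 9L, 22L)))
  sp <- project_char_spans(doc)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$sent, c(1L, 2L))
  for (i in seq_len(nrow(sp))) {
    ch <- kgfuse:::token_span_to_chars(doc, sp$sent[i], sp$start[i],
                                       sp$end[i])
    s <- doc$sentences[[sp$sent[i]]]
    frag_lo <- max(doc$annotations$start[1], min(s$starts))
    frag_hi <- min(doc$annotations$end[1], max(s$ends))
    expect_lte(ch[1], frag_lo)
    expect_gte(ch[2], frag_hi)
  }
})

test_that("generated corpora survive every reader/writer", {
  inp <- tiny_experiment_inputs(seed = 9L, n_docs = 4L)
  dir <- withr::local_tempdir()
  write_brat(inp$corpus, dir)
  for (id in names(inp$corpus)) {
    doc <- read_brat(file.path(dir, paste0(id, ".txt")),
                     file.path(dir, paste0(id, ".ann")))
    expect_equal(doc$text, inp$corpus[[id]]$text)
    expect_equal(nrow(doc$annotations), nrow(inp$corpus[[id]]$annotations))
  }
  iob <- corpus_to_iob(inp$corpus)
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll_iob(iob, path)
  expect_equal(length(read_conll_iob(path)), length(inp$corpus))
})
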