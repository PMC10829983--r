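test_that("load_document reads UTF-8 text and normalises line endings", {
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines(character(0), f)
  expect_identical(load_document(f)$body, "")

  sent <- paste("Asthma is a heterogeneous disease, usually characterized",
                "by chronic airway inflammation.")
  writeLines(sent, f)
  doc <- load_document(f)
  expect_true(grepl(sent, doc$body, fixed = TRUE))
  expect_identical(doc$doc_id, sub("\\.txt$", "", basename(f)))

  # CRLF and bare CR both collapse to LF; oracle = hand-normalised copy
  writeBin(charToRaw("line one\r\nline two\rline three\n"), f)
  expect_identical(load_document(f)$body, "line one\nline two\nline three\n")
})

test_that("load_document rejects missing files and invalid UTF-8 with offset", {
  expect_error(load_document(file.path(tempdir(), "no-such-file.txt")),
               "input error")
  f <- withr::local_tempfile(fileext = ".txt")
  writeBin(as.raw(c(0x61, 0x62, 0xFF, 0x63)), f)
  expect_error(load_document(f), "offset 2")
})

test_that("segment_sentences splits, orders and stamps provenance", {
  f <- withr::local_tempfile(fileext = ".txt")
  s1 <- "Specific questions for assessment of asthma in children."
  s2 <- "Asthma is a heterogeneous disease."
  writeLines(c(s1, "", s2), f)
  doc <- load_document(f, doc_id = "gina")
  sents <- segment_sentences(doc)
  expect_length(sents, 2L)
  expect_identical(vapply(sents, `[[`, character(1), "raw"), c(s1, s2))
  expect_identical(vapply(sents, `[[`, character(1), "doc_id"),
                   c("gina", "gina"))
  expect_identical(vapply(sents, `[[`, integer(1), "sent_index"), 0:1)

  empty <- structure(list(doc_id = "e", body = "", source_path = ""),
                     class = "mlr_document")
  expect_identical(segment_sentences(empty), list())

  failing <- function(text, doc_id) stop("backend down")
  expect_error(segment_sentences(doc, tagger = failing), "gina")
})

test_that("fixture-generated corpora have the sentence count the manifest records", {
  for (seed in c(2, 11)) {
    fx <- generate_fixture(fixture_config(n_sentences = 60, seed = seed))
    expect_length(fx$corpus, unname(fx$manifest$counts["n_sentences"]))
    expect_identical(vapply(fx$corpus, `[[`, integer(1), "sent_index"),
                     seq_along(fx$corpus) - 1L)
  }
})

test_that("tagged sentences satisfy the token invariants", {
  tag <- fixture_tagger()
  sents <- tag("Severe asthma worsens sleep. Budesonide reduces inflammation.",
               "d1")
  for (s in sents) {
    tk <- s$tokens
    expect_identical(tk$index, seq_len(nrow(tk)) - 1L)
    expect_identical(sum(tk$dep == "root"), 1L)
    root <- which(tk$dep == "root")
    expect_identical(tk$head[root], tk$index[root])
    expect_true(all(tk$head >= 0 & tk$head < nrow(tk)))
  }
  # invariant violations are rejected at construction
  bad <- data.frame(index = 0:1, surface = c("a", "b"), lemma = c("a", "b"),
                    pos = "noun", dep = c("root", "root"), head = c(0L, 1L))
  expect_error(new_sentence("d", 0L, bad, "a b"), "exactly one root")
})

test_that("tagged-record files round-trip bijectively", {
  f <- withr::local_tempfile(fileext = ".jsonl")

  writeLines(character(0), f)
  expect_identical(read_tagged_records(f), list())

  # hand-written 3-token record, parsed manually as the oracle
  lines <- c(
    '{"doc_id":"h","sent_index":0,"index":0,"surface":"Asthma","lemma":"asthma","pos":"noun","dep":"subject","head":1,"sent_break":true,"raw":"Asthma worsens sleep."}',
    '{"doc_id":"h","sent_index":0,"index":1,"surface":"worsens","lemma":"worsens","pos":"verb","dep":"root","head":1,"sent_break":false}',
    '{"doc_id":"h","sent_index":0,"index":2,"surface":"sleep","lemma":"sleep","pos":"noun","dep":"direct-object","head":1,"sent_break":false}')
  writeLines(lines, f)
  sents <- read_tagged_records(f)
  expect_length(sents, 1L)
  expect_identical(nrow(sents[[1]]$tokens), 3L)
  expect_identical(sents[[1]]$tokens$surface, c("Asthma", "worsens", "sleep"))
  expect_identical(sents[[1]]$raw, "Asthma worsens sleep.")

  # write -> read is the identity on a random fixture corpus
  fx <- generate_fixture(fixture_config(n_sentences = 40, seed = 5))
  write_tagged_records(fx$corpus, f)
  back <- read_tagged_records(f)
  expect_equal(back, fx$corpus)

  writeLines("{not json", f)
  expect_error(read_tagged_records(f), "line 1")
})
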