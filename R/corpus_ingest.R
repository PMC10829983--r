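#' Load a plain-text article
#'
#' Reads a UTF-8 text file into a document record. Line endings are
#' normalised to `"\n"` (CRLF and bare CR both become LF) so downstream
#' sentence segmentation sees one convention.
#'
#' @param path path to a UTF-8 `.txt` file.
#' @param doc_id document identifier; defaults to the file name without
#'   extension.
#' @return an object of class `mlr_document`: a list with `doc_id`, `body`
#'   and `source_path`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("Asthma is a heterogeneous disease.", f)
#' doc <- load_document(f)
#' doc$doc_id
load_document <- function(path, doc_id = NULL) {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.size(path))
  bad <- utf8_invalid_offset(raw)
  if (!is.na(bad)) {
    stop("encoding error: invalid UTF-8 byte at offset ", bad,
         " in ", path, call. = FALSE)
  }
  body <- rawToChar(raw)
  Encoding(body) <- "UTF-8"
  body <- gsub("\r\n", "\n", body, fixed = TRUE)
  body <- gsub("\r", "\n", body, fixed = TRUE)
  if (is.null(doc_id)) {
    doc_id <- sub("\\.[^.]*$", "", basename(path))
  }
  stopifnot(nzchar(doc_id))
  structure(list(doc_id = doc_id, body = body, source_path = path),
            class = "mlr_document")
}

# 0-based byte offset of the first invalid UTF-8 byte, or NA if valid.
utf8_invalid_offset <- function(raw) {
  n <- length(raw)
  b <- as.integer(raw)
  i <- 1L
  while (i <= n) {
    x <- b[i]
    len <- if (x < 0x80L) 1L
      else if (x >= 0xC2L && x <= 0xDFL) 2L
      else if (x >= 0xE0L && x <= 0xEFL) 3L
      else if (x >= 0xF0L && x <= 0xF4L) 4L
      else return(i - 1L)
    if (i + len - 1L > n) return(i - 1L)
    if (len > 1L) {
      cont <- b[(i + 1L):(i + len - 1L)]
      if (any(cont < 0x80L | cont > 0xBFL)) return(i - 1L)
      # reject overlong / surrogate / out-of-range leads
      if (x == 0xE0L && b[i + 1L] < 0xA0L) return(i - 1L)
      if (x == 0xEDL && b[i + 1L] > 0x9FL) return(i - 1L)
      if (x == 0xF0L && b[i + 1L] < 0x90L) return(i - 1L)
      if (x == 0xF4L && b[i + 1L] > 0x8FL) return(i - 1L)
    }
    i <- i + len
  }
  NA_integer_
}

#' Construct a tagged sentence
#'
#' A sentence is an ordered token table plus provenance. Token invariants
#' (contiguous 0-based indices, exactly one root whose head is itself, all
#' heads in bounds) are checked on construction.
#'
#' @param doc_id document identifier.
#' @param sent_index 0-based sentence position within the document.
#' @param tokens data frame with columns `index`, `surface`, `lemma`, `pos`,
#'   `dep`, `head`. `pos` uses the coarse set noun/verb/adjective/adposition/
#'   determiner/other; `dep` the closed set subject/passive-subject/
#'   direct-object/prepositional-object/attribute/compound/modifier/particle/
#'   root/other.
#' @param raw original sentence text.
#' @return an object of class `mlr_sentence`.
#' @export
new_sentence <- function(doc_id, sent_index, tokens, raw) {
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  s <- structure(list(doc_id = doc_id, sent_index = as.integer(sent_index),
                      tokens = tokens, raw = raw),
                 class = "mlr_sentence")
  validate_sentence(s)
  s
}

POS_SET <- c("noun", "verb", "adjective", "adposition", "determiner", "other")
DEP_SET <- c("subject", "passive-subject", "direct-object",
             "prepositional-object", "attribute", "compound", "modifier",
             "particle", "root", "other")

validate_sentence <- function(s) {
  tk <- s$tokens
  n <- nrow(tk)
  if (n == 0L) stop("sentence has no tokens (doc ", s$doc_id, ")", call. = FALSE)
  if (!identical(as.integer(tk$index), seq_len(n) - 1L)) {
    stop("token indices not contiguous 0..", n - 1L, " (doc ", s$doc_id,
         ", sentence ", s$sent_index, ")", call. = FALSE)
  }
  if (any(tk$head < 0L | tk$head >= n)) {
    stop("token head out of bounds (doc ", s$doc_id, ", sentence ",
         s$sent_index, ")", call. = FALSE)
  }
  roots <- which(tk$dep == "root")
  if (length(roots) != 1L) {
    stop("sentence must have exactly one root token, found ", length(roots),
         " (doc ", s$doc_id, ", sentence ", s$sent_index, ")", call. = FALSE)
  }
  if (tk$head[roots] != tk$index[roots]) {
    stop("root token's head must be itself (doc ", s$doc_id, ", sentence ",
         s$sent_index, ")", call. = FALSE)
  }
  bad_pos <- setdiff(unique(tk$pos), POS_SET)
  bad_dep <- setdiff(unique(tk$dep), DEP_SET)
  if (length(bad_pos)) stop("unknown pos label(s): ",
                            paste(bad_pos, collapse = ", "), call. = FALSE)
  if (length(bad_dep)) stop("unknown dep label(s): ",
                            paste(bad_dep, collapse = ", "), call. = FALSE)
  invisible(s)
}

#' @export
print.mlr_sentence <- function(x, ...) {
  cat("<sentence ", x$doc_id, "#", x$sent_index, "> ", x$raw, "\n", sep = "")
  invisible(x)
}

#' Segment a document into tagged sentences
#'
#' Runs a tagger over the document body. A tagger is any function with
#' signature `function(text, doc_id)` returning a list of `mlr_sentence`
#' objects — the packaged [fixture_tagger()] or a wrapper around a real NLP
#' backend both qualify. Every returned sentence is re-validated and its
#' `doc_id` forced to the document's.
#'
#' @param doc an `mlr_document` from [load_document()].
#' @param tagger a tagger function; defaults to [fixture_tagger()].
#' @return list of `mlr_sentence`, ordered by position.
#' @export
segment_sentences <- function(doc, tagger = fixture_tagger()) {
  stopifnot(inherits(doc, "mlr_document"))
  if (!nzchar(trimws(doc$body))) return(list())
  sents <- tryCatch(tagger(doc$body, doc$doc_id),
                    error = function(e) {
                      stop("tagger failed on document '", doc$doc_id, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  for (i in seq_along(sents)) {
    sents[[i]]$doc_id <- doc$doc_id
    sents[[i]]$sent_index <- i - 1L
    validate_sentence(sents[[i]])
  }
  sents
}

#' Rule-based fixture tagger
#'
#' A deterministic tagger for tests and demonstrations: no model download,
#' same output on every run. Sentences are split on `.`, `!` or `?` followed
#' by whitespace (or end of text). Within a sentence, tokens are whitespace
#' words with trailing punctuation stripped; tagging is lexicon-driven:
#'
#' * the first token found in `verbs` becomes the root verb;
#' * the last pre-verb token is the subject head, earlier pre-verb tokens
#'   are `compound` children of it;
#' * a post-verb token in `adpositions` becomes an adposition headed by the
#'   verb (yielding prepositional objects such as "binds to");
#' * the last remaining post-verb token is the object head (`direct-object`
#'   under the verb, or `prepositional-object` under the adposition), with
#'   earlier post-verb tokens as its `compound` children;
#' * a sentence with no lexicon verb gets a nominal root and yields no
#'   triplets.
#'
#' @param verbs character vector of verb surfaces recognised as predicates.
#' @param adpositions character vector of adpositions that attach objects.
#' @return a tagger function `function(text, doc_id)`.
#' @export
#' @examples
#' tag <- fixture_tagger(verbs = "binds", adpositions = "to")
#' s <- tag("Reslizumab benralizumab binds to cell eosinophils.", "demo")
#' s[[1]]$tokens
fixture_tagger <- function(verbs = default_fixture_lexicon()$verbs,
                           adpositions = default_fixture_lexicon()$adpositions) {
  force(verbs); force(adpositions)
  function(text, doc_id = "doc") {
    raw_sents <- split_fixture_sentences(text)
    out <- vector("list", length(raw_sents))
    for (i in seq_along(raw_sents)) {
      out[[i]] <- tag_fixture_sentence(raw_sents[[i]], doc_id, i - 1L,
                                       verbs, adpositions)
    }
    out[!vapply(out, is.null, logical(1))]
  }
}

split_fixture_sentences <- function(text) {
  text <- gsub("\\s+", " ", trimws(text))
  if (!nzchar(text)) return(character(0))
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

tag_fixture_sentence <- function(raw, doc_id, sent_index, verbs, adpositions) {
  words <- strsplit(trimws(raw), "\\s+")[[1]]
  surfaces <- gsub("[.!?,;:]+$", "", words)
  keep <- nzchar(surfaces)
  surfaces <- surfaces[keep]
  n <- length(surfaces)
  if (n == 0L) return(NULL)

  idx <- seq_len(n) - 1L
  pos <- rep("noun", n)
  dep <- rep("other", n)
  head <- integer(n)

  v <- match(TRUE, tolower(surfaces) %in% tolower(verbs))
  if (is.na(v)) {
    # no predicate: nominal fragment, first token is root
    dep[1L] <- "root"
    head[] <- 0L
  } else {
    pos[v] <- "verb"
    dep[v] <- "root"
    head[v] <- v - 1L
    if (v > 1L) {
      sub_head <- v - 1L                      # last pre-verb token
      dep[sub_head] <- "subject"
      head[sub_head] <- v - 1L
      if (sub_head > 1L) {
        pre <- seq_len(sub_head - 1L)
        dep[pre] <- "compound"
        head[pre] <- sub_head - 1L
      }
    }
    if (v < n) {
      post_start <- v + 1L
      adp <- NA_integer_
      if (tolower(surfaces[post_start]) %in% tolower(adpositions)) {
        adp <- post_start
        pos[adp] <- "adposition"
        dep[adp] <- "particle"
        head[adp] <- v - 1L
        post_start <- post_start + 1L
      }
      if (post_start <= n) {
        obj_head <- n
        if (is.na(adp)) {
          dep[obj_head] <- "direct-object"
          head[obj_head] <- v - 1L
        } else {
          dep[obj_head] <- "prepositional-object"
          head[obj_head] <- adp - 1L
        }
        if (obj_head > post_start) {
          mid <- post_start:(obj_head - 1L)
          dep[mid] <- "compound"
          head[mid] <- obj_head - 1L
        }
      }
    }
  }

  tokens <- data.frame(index = idx, surface = surfaces,
                       lemma = tolower(surfaces), pos = pos, dep = dep,
                       head = head, stringsAsFactors = FALSE)
  new_sentence(doc_id, sent_index, tokens, trimws(raw))
}

default_fixture_lexicon <- function() {
  path <- system.file("extdata", "fixture_vocabulary.json", package = "mlrkg")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write tagged sentences as JSON Lines
#'
#' One token object per line with the token fields plus provenance;
#' `sent_break: true` marks the first token of each sentence, which also
#' carries the sentence's `raw` text. [read_tagged_records()] inverts this
#' exactly.
#'
#' @param sentences list of `mlr_sentence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tagged_records <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    tk <- s$tokens
    for (j in seq_len(nrow(tk))) {
      rec <- list(doc_id = s$doc_id, sent_index = s$sent_index,
                  index = tk$index[j], surface = tk$surface[j],
                  lemma = tk$lemma[j], pos = tk$pos[j], dep = tk$dep[j],
                  head = tk$head[j], sent_break = (j == 1L))
      if (j == 1L) rec$raw <- s$raw
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read tagged sentences from JSON Lines
#'
#' @param path file written by [write_tagged_records()] (or any conforming
#'   line-record file).
#' @return list of `mlr_sentence`.
#' @export
read_tagged_records <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                          error = function(e) {
                            stop("parse error at line ", i, ": ",
                                 conditionMessage(e), call. = FALSE)
                          })
    need <- c("doc_id", "sent_index", "index", "surface", "lemma", "pos",
              "dep", "head", "sent_break")
    missing <- setdiff(need, names(recs[[i]]))
    if (length(missing)) {
      stop("parse error at line ", i, ": missing field(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  breaks <- which(vapply(recs, function(r) isTRUE(r$sent_break), logical(1)))
  if (length(breaks) == 0L || breaks[1] != 1L) {
    stop("parse error at line 1: first record must have sent_break=true",
         call. = FALSE)
  }
  ends <- c(breaks[-1] - 1L, length(recs))
  out <- vector("list", length(breaks))
  for (k in seq_along(breaks)) {
    chunk <- recs[breaks[k]:ends[k]]
    tokens <- data.frame(
      index = vapply(chunk, function(r) as.integer(r$index), integer(1)),
      surface = vapply(chunk, function(r) as.character(r$surface), character(1)),
      lemma = vapply(chunk, function(r) as.character(r$lemma), character(1)),
      pos = vapply(chunk, function(r) as.character(r$pos), character(1)),
      dep = vapply(chunk, function(r) as.character(r$dep), character(1)),
      head = vapply(chunk, function(r) as.integer(r$head), integer(1)),
      stringsAsFactors = FALSE)
    out[[k]] <- new_sentence(chunk[[1]]$doc_id,
                             as.integer(chunk[[1]]$sent_index), tokens,
                             chunk[[1]]$raw %||% "")
  }
  out
}
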