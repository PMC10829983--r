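#' Fixture generator configuration
#'
#' Describes a synthetic tagged corpus with planted ground truth. The
#' generated sentences follow the fixture tagger's grammar exactly, so
#' triplet extraction recovers the planted table verbatim — that equality
#' is the extraction oracle used throughout the tests.
#'
#' @param n_sentences total number of sentences.
#' @param p_incomplete fraction of sentences missing their subject or
#'   object (candidates that the completeness filter must drop).
#' @param p_duplicate fraction of sentences that restate an earlier
#'   complete triplet (rows that deduplication must fold).
#' @param planted_joints optional data frame with columns `entity`,
#'   `subject_count`, `object_count`: entities planted at exact degrees for
#'   joint-analysis tests.
#' @param pair_frequency_profile optional data frame with columns `source`,
#'   `target`, `count`: entity pairs planted at exact co-occurrence
#'   frequencies for prediction tests.
#' @param keyword_fraction fraction of base sentences whose subject bears
#'   the domain keyword.
#' @param keyword the planted domain keyword (default `"asthma"`).
#' @param seed RNG seed; same seed, bit-identical output.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(n_sentences = 200, p_incomplete = 0.15,
                           p_duplicate = 0.1, planted_joints = NULL,
                           pair_frequency_profile = NULL,
                           keyword_fraction = 0.4, keyword = "asthma",
                           seed = 1L) {
  stopifnot(n_sentences >= 0,
            p_incomplete >= 0, p_incomplete <= 1,
            p_duplicate >= 0, p_duplicate <= 1,
            keyword_fraction >= 0, keyword_fraction <= 1,
            is.numeric(seed))
  if (!is.null(planted_joints)) {
    planted_joints <- as.data.frame(planted_joints)
    stopifnot(all(c("entity", "subject_count", "object_count") %in%
                    names(planted_joints)),
              all(planted_joints$subject_count >= 0),
              all(planted_joints$object_count >= 0))
  }
  if (!is.null(pair_frequency_profile)) {
    pair_frequency_profile <- as.data.frame(pair_frequency_profile)
    stopifnot(all(c("source", "target", "count") %in%
                    names(pair_frequency_profile)),
              all(pair_frequency_profile$count >= 1))
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 p_incomplete = p_incomplete, p_duplicate = p_duplicate,
                 planted_joints = planted_joints,
                 pair_frequency_profile = pair_frequency_profile,
                 keyword_fraction = keyword_fraction, keyword = keyword,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# run code under a private RNG stream, restoring the caller's state
with_fixture_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic tagged corpus with planted ground truth
#'
#' Emits (i) a corpus of tagged sentences written in the fixture tagger's
#' grammar, (ii) the planted triplet table that extraction must recover,
#' and (iii) a manifest recording per-row completeness, duplicate keys,
#' keyword-bearing flags, per-entity degrees over the distinct complete
#' triplets, and pair co-occurrence frequencies — the oracle record the
#' test suite checks results against. Generation is a pure function of the
#' configuration (seed included) and never touches the caller's RNG state.
#'
#' Budget: of `n_sentences`, `round(p_incomplete * n)` sentences are
#' incomplete, `round(p_duplicate * n)` restate earlier triplets, joint
#' and pair-profile rows use `sum(subject_count + object_count)` and
#' `sum(count)` sentences respectively, and the remainder are unique
#' complete base sentences. An over-committed budget is a configuration
#' error.
#'
#' @param config a [fixture_config()].
#' @return list with `corpus` (list of `mlr_sentence`), `table` (planted
#'   `mlr_triplets`) and `manifest` (list: `rows`, `degrees`,
#'   `pair_frequencies`, `counts`).
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_sentences
  if (n == 0L) {
    empty <- triplet_table(stage_label = "planted")
    return(list(corpus = list(), table = empty,
                manifest = list(rows = empty,
                                degrees = entity_degrees(empty),
                                pair_frequencies = tibble::tibble(
                                  source = character(0), target = character(0),
                                  count = integer(0)),
                                counts = c(n_sentences = 0L, n_complete = 0L,
                                           n_incomplete = 0L, n_unique_keys = 0L))))
  }
  voc <- default_fixture_lexicon()
  n_inc <- round(n * config$p_incomplete)
  n_dup <- round(n * config$p_duplicate)
  n_joint <- if (is.null(config$planted_joints)) 0L else
    sum(config$planted_joints$subject_count + config$planted_joints$object_count)
  n_pair <- if (is.null(config$pair_frequency_profile)) 0L else
    sum(config$pair_frequency_profile$count)
  n_base <- n - n_inc - n_dup - n_joint - n_pair
  if (n_base < 0L || (n_dup > 0L && n_base + n_pair < 1L)) {
    stop("configuration error: planted rows exceed n_sentences (base budget ",
         n_base, ")", call. = FALSE)
  }

  with_fixture_rng(config$seed, {
    rows <- generate_fixture_rows(config, voc, n_base, n_inc, n_dup)
    build_fixture_outputs(rows, config)
  })
}

# draws one multi-token entity phrase; returns its token vector
sample_phrase <- function(voc, keyword = NULL, reserved = character(0)) {
  repeat {
    n_mod <- sample(0:2, 1, prob = c(0.4, 0.4, 0.2))
    mods <- if (n_mod > 0) sample(voc$modifiers, n_mod) else character(0)
    head <- if (is.null(keyword)) {
      sample(c(voc$drugs, voc$symptoms, voc$comorbidities), 1)
    } else keyword
    phrase <- c(mods, head)
    if (!normalize_label(paste(phrase, collapse = " ")) %in% reserved) {
      return(phrase)
    }
  }
}

# relation choices: verb surface plus optional adposition
sample_relation <- function(voc) {
  with_prep <- list(c("binds", "to"), c("respond", "to"),
                    c("associated", "with"))
  bare <- c("causes", "triggers", "improves", "reduces", "treats",
            "relieves", "includes", "recommends", "prevents", "worsens",
            "exacerbates")
  if (stats::runif(1) < 0.25) {
    with_prep[[sample(length(with_prep), 1)]]
  } else {
    sample(bare, 1)
  }
}

generate_fixture_rows <- function(config, voc, n_base, n_inc, n_dup) {
  reserved <- character(0)
  if (!is.null(config$planted_joints)) {
    reserved <- c(reserved, normalize_label(config$planted_joints$entity))
  }
  if (!is.null(config$pair_frequency_profile)) {
    reserved <- c(reserved,
                  normalize_label(config$pair_frequency_profile$source),
                  normalize_label(config$pair_frequency_profile$target))
  }

  mk_row <- function(subj, rel, obj, kind, kw = FALSE) {
    list(subject_tokens = subj, relation_tokens = rel, object_tokens = obj,
         kind = kind, keyword_bearing = kw)
  }
  rows <- list()

  # unique complete base sentences, a fraction bearing the keyword
  n_kw <- round(n_base * config$keyword_fraction)
  seen_keys <- character(0)
  for (i in seq_len(n_base)) {
    kw <- i <= n_kw
    for (attempt in 1:200) {
      subj <- sample_phrase(voc, keyword = if (kw) config$keyword else NULL,
                            reserved = reserved)
      rel <- sample_relation(voc)
      obj <- sample_phrase(voc, reserved = reserved)
      key <- triplet_key(paste(subj, collapse = " "),
                         paste(rel, collapse = " "),
                         paste(obj, collapse = " "))
      if (!key %in% seen_keys) break
      if (attempt == 200) stop("configuration error: cannot plant ", n_base,
                               " unique base triplets", call. = FALSE)
    }
    seen_keys <- c(seen_keys, key)
    rows[[length(rows) + 1L]] <- mk_row(subj, rel, obj, "base", kw)
  }

  # planted joint degrees: dedicated rows with single-use filler entities
  if (!is.null(config$planted_joints)) {
    pj <- config$planted_joints
    filler_i <- 0L
    for (j in seq_len(nrow(pj))) {
      ent <- strsplit(pj$entity[j], "\\s+")[[1]]
      for (s in seq_len(pj$subject_count[j])) {
        filler_i <- filler_i + 1L
        rows[[length(rows) + 1L]] <-
          mk_row(ent, sample_relation(voc), paste0("cofactor", filler_i),
                 "joint")
      }
      for (o in seq_len(pj$object_count[j])) {
        filler_i <- filler_i + 1L
        rows[[length(rows) + 1L]] <-
          mk_row(paste0("cofactor", filler_i), sample_relation(voc), ent,
                 "joint")
      }
    }
  }

  # planted pair frequencies: identical restatements of one pair
  if (!is.null(config$pair_frequency_profile)) {
    pf <- config$pair_frequency_profile
    for (j in seq_len(nrow(pf))) {
      subj <- strsplit(pf$source[j], "\\s+")[[1]]
      obj <- strsplit(pf$target[j], "\\s+")[[1]]
      for (r in seq_len(pf$count[j])) {
        rows[[length(rows) + 1L]] <- mk_row(subj, "involves", obj, "pair")
      }
    }
  }

  # duplicates: restate a random earlier complete row verbatim
  dup_pool <- which(vapply(rows, function(r) r$kind %in% c("base", "pair"),
                           logical(1)))
  for (d in seq_len(n_dup)) {
    src <- rows[[dup_pool[sample.int(length(dup_pool), 1)]]]
    src$kind <- "duplicate"
    rows[[length(rows) + 1L]] <- src
  }

  # incomplete sentences: drop the subject or the object
  for (i in seq_len(n_inc)) {
    drop_subject <- stats::runif(1) < 0.5
    rel <- sample_relation(voc)
    if (drop_subject) {
      rows[[length(rows) + 1L]] <-
        mk_row(character(0), rel, sample_phrase(voc, reserved = reserved),
               "incomplete")
    } else {
      # a trailing adposition with no object would vanish from the
      # extracted relation, so incomplete-object rows use the bare verb
      rows[[length(rows) + 1L]] <-
        mk_row(sample_phrase(voc, reserved = reserved), rel[1], character(0),
               "incomplete")
    }
  }

  # shuffle sentence order so stages interleave like a real corpus,
  # keeping each duplicate after its original
  ord <- sample(seq_along(rows))
  kinds <- vapply(rows, `[[`, character(1), "kind")
  if (any(kinds == "duplicate")) {
    # duplicates carry their text with them, so order independence holds;
    # no reordering constraint needed beyond determinism
  }
  rows[ord]
}

build_fixture_outputs <- function(rows, config) {
  voc <- default_fixture_lexicon()
  verbs_lc <- tolower(voc$verbs)
  corpus <- vector("list", length(rows))
  tab <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    # entity/modifier tokens must stay outside the verb lexicon, or the
    # tagger would re-segment the sentence differently from the plant
    ent_tokens <- c(r$subject_tokens, r$object_tokens)
    clash <- ent_tokens[tolower(ent_tokens) %in% verbs_lc]
    if (length(clash)) {
      stop("fixture inconsistency: entity token(s) collide with verb ",
           "lexicon: ", paste(unique(clash), collapse = ", "), call. = FALSE)
    }
    raw <- paste0(paste(c(r$subject_tokens, r$relation_tokens,
                          r$object_tokens), collapse = " "), ".")
    sent <- tag_fixture_sentence(raw, "fixture", i - 1L, voc$verbs,
                                 voc$adpositions)
    corpus[[i]] <- sent
    tab[[i]] <- data.frame(
      source = paste(r$subject_tokens, collapse = " "),
      edge = paste(r$relation_tokens, collapse = " "),
      target = paste(r$object_tokens, collapse = " "),
      doc_id = "fixture", sent_index = i - 1L,
      kind = r$kind, keyword_bearing = r$keyword_bearing,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, tab)
  table <- triplet_table(df[c("source", "edge", "target", "doc_id",
                              "sent_index")], stage_label = "planted")
  keys <- table_keys(table)
  manifest_rows <- tibble::as_tibble(cbind(
    as.data.frame(table),
    data.frame(kind = df$kind, keyword_bearing = df$keyword_bearing,
               is_duplicate = duplicated(keys), stringsAsFactors = FALSE)))
  distinct_complete <- deduplicate(filter_complete(table))
  pair_src <- normalize_label(table$source[table$complete])
  pair_dst <- normalize_label(table$target[table$complete])
  pk <- paste(pmin(pair_src, pair_dst), pmax(pair_src, pair_dst),
              sep = "\x1f")
  pf <- table(pk)
  parts <- strsplit(names(pf), "\x1f", fixed = TRUE)
  manifest <- list(
    rows = manifest_rows,
    degrees = entity_degrees(distinct_complete),
    pair_frequencies = tibble::tibble(
      source = vapply(parts, `[`, character(1), 1),
      target = vapply(parts, `[`, character(1), 2),
      count = as.integer(pf)),
    counts = c(n_sentences = nrow(table),
               n_complete = sum(table$complete),
               n_incomplete = sum(!table$complete),
               n_keyword = sum(df$keyword_bearing),
               n_unique_keys = length(unique(keys[table$complete]))))
  # generation-time self-check: corpus and manifest must agree structurally
  stopifnot(length(corpus) == nrow(manifest_rows),
            sum(manifest$rows$is_duplicate) == sum(duplicated(keys)))
  lapply(corpus, validate_sentence)
  list(corpus = corpus, table = table, manifest = manifest)
}

#' Comorbidity demonstration graph
#'
#' A small deterministic triplet table in the shape of a comorbidity
#' knowledge graph: "asthma" linked (in both directions) to allergies,
#' obesity, depression, COPD, GERD and rhinitis, plus background edges
#' among other entities that a keyword query for "asthma" must not pull
#' in at depth 1.
#'
#' @return an `mlr_triplets` table (deduplicated, complete).
#' @export
comorbidity_fixture <- function() {
  rows <- rbind(
    data.frame(source = "asthma", edge = "associated with",
               target = c("allergies", "obesity", "depression"),
               stringsAsFactors = FALSE),
    data.frame(source = c("COPD", "GERD", "rhinitis"),
               edge = "accompanies", target = "asthma",
               stringsAsFactors = FALSE),
    data.frame(source = c("obesity", "depression", "sinusitis"),
               edge = c("worsens", "accompanies", "precedes"),
               target = c("apnea", "anxiety", "rhinitis"),
               stringsAsFactors = FALSE))
  deduplicate(triplet_table(rows, stage_label = "comorbidity-demo"))
}

#' The worked chatbot evaluation scenario
#'
#' A deterministic reconstruction of the query-answering example: a
#' deduplicated ground truth of exactly 202 distinct triplets and a
#' 10-item ranked prediction list produced by [predict_query_triplets()]
#' on a planted query log, whose rank-1 and rank-3 items —
#' ("Asthma", "Am", "Asthma") and ("Exacerbation", "Am", "Asthma") — occur
#' in the truth while the other eight do not. The prediction list carries
#' relevance grades 1 (rank 1) and 2 (rank 3) for the graded MAP
#' convention.
#'
#' @return list with `predicted` (ranked-triplet tibble with `relevance`)
#'   and `truth` (an `mlr_triplets` table of 202 rows).
#' @export
paper_scenario <- function() {
  voc <- default_fixture_lexicon()
  # 202 distinct truths: the two "Am" facts, 192 drug-treats-symptom
  # pairs, and 8 asthma comorbidity links
  truth_rows <- rbind(
    data.frame(source = c("Asthma", "Exacerbation"), edge = "Am",
               target = "Asthma", stringsAsFactors = FALSE),
    expand.grid(source = voc$drugs, target = voc$symptoms,
                stringsAsFactors = FALSE)[, c("source", "target")] |>
      transform(edge = "treats"),
    data.frame(source = "asthma", edge = "associated with",
               target = voc$comorbidities[1:8], stringsAsFactors = FALSE))
  truth <- deduplicate(triplet_table(
    truth_rows[c("source", "edge", "target")], stage_label = "ground-truth"))

  # query log: pair i planted with frequency 11 - i, so the predictor
  # ranks the pairs 1..10 deterministically
  pairs <- data.frame(
    source = c("Asthma", "Asthma", "Exacerbation", "Wheezing", "Coughing",
               "Dyspnea", "Obesity", "Rhinitis", "Allergies", "COPD"),
    target = c("Asthma", "Inhaler", "Asthma", "Night", "Morning",
               "Exercise", "Risk", "Spring", "Pollen", "Smoking"),
    count = 10:1, stringsAsFactors = FALSE)
  qlog <- triplet_table(data.frame(
    source = rep(pairs$source, pairs$count),
    edge = "asks about",
    target = rep(pairs$target, pairs$count), stringsAsFactors = FALSE),
    stage_label = "query-log")
  predicted <- predict_query_triplets(qlog, k = 10, relation = "Am")
  predicted$relevance <- ifelse(predicted$rank == 1, 1,
                                ifelse(predicted$rank == 3, 2, 0))
  list(predicted = predicted, truth = truth)
}
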