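#' Extract a multi-word entity phrase around a head token
#'
#' Collects the head token together with every `compound`/`modifier` token
#' whose head chain reaches `head_index` without passing through a verb, and
#' joins the members in sentence order. This is how single tokens like
#' "eosinophils" grow into phrases like "cell eosinophils".
#'
#' @param sentence an `mlr_sentence`.
#' @param head_index 0-based index of the phrase head token.
#' @return a list with `head_index`, `member_indices` (sorted, 0-based),
#'   `surface` (members joined by single spaces in sentence order) and
#'   `normalized` (see [normalize_label()]).
#' @export
extract_entity_phrase <- function(sentence, head_index) {
  tk <- sentence$tokens
  n <- nrow(tk)
  stopifnot(head_index >= 0L, head_index < n)
  members <- head_index
  for (i in seq_len(n) - 1L) {
    if (i == head_index) next
    if (!tk$dep[i + 1L] %in% c("compound", "modifier")) next
    # walk the head chain; stop at a verb or a cycle
    j <- i
    seen <- integer(0)
    reached <- FALSE
    while (!(j %in% seen)) {
      seen <- c(seen, j)
      j <- tk$head[j + 1L]
      if (j == head_index) { reached <- TRUE; break }
      if (tk$pos[j + 1L] == "verb") break
    }
    if (reached) members <- c(members, i)
  }
  members <- sort(members)
  surface <- paste(tk$surface[members + 1L], collapse = " ")
  list(head_index = head_index, member_indices = members,
       surface = surface, normalized = normalize_label(surface))
}

#' Extract candidate triplets from one tagged sentence
#'
#' For each verb token V, emits one (subject, relation, object) candidate:
#' the subject is the phrase of the first `subject`/`passive-subject` token
#' headed by V; the object is the phrase of the first `direct-object`/
#' `attribute` token headed by V, or failing that the first
#' `prepositional-object` reachable through one adposition headed by V, in
#' which case the adposition surface is suffixed to the relation ("binds
#' to"). A candidate is emitted even when a slot is empty — the completeness
#' filter removes those later, and their count is part of the refinement
#' bookkeeping.
#'
#' @param sentence an `mlr_sentence`.
#' @param lemma_relations if `TRUE`, relations use the verb lemma instead of
#'   its surface form.
#' @return a triplet table (see [triplet_table()]) with zero or more rows.
#' @export
extract_triplets <- function(sentence, lemma_relations = FALSE) {
  tk <- sentence$tokens
  verb_idx <- which(tk$pos == "verb") - 1L
  rows <- lapply(verb_idx, function(v) {
    headed_by_v <- which(tk$head == v & tk$index != v) - 1L

    subj_tok <- headed_by_v[tk$dep[headed_by_v + 1L] %in%
                              c("subject", "passive-subject")]
    subj <- if (length(subj_tok)) {
      extract_entity_phrase(sentence, subj_tok[1L])$surface
    } else ""

    rel <- if (lemma_relations) tk$lemma[v + 1L] else tk$surface[v + 1L]
    obj_tok <- headed_by_v[tk$dep[headed_by_v + 1L] %in%
                             c("direct-object", "attribute")]
    obj <- ""
    if (length(obj_tok)) {
      obj <- extract_entity_phrase(sentence, obj_tok[1L])$surface
    } else {
      adp <- headed_by_v[tk$pos[headed_by_v + 1L] == "adposition"]
      for (a in adp) {
        pobj <- which(tk$head == a & tk$dep == "prepositional-object") - 1L
        if (length(pobj)) {
          obj <- extract_entity_phrase(sentence, pobj[1L])$surface
          rel <- paste(rel, tk$surface[a + 1L])
          break
        }
      }
    }

    data.frame(source = subj, edge = rel, target = obj,
               doc_id = sentence$doc_id, sent_index = sentence$sent_index,
               stringsAsFactors = FALSE)
  })
  triplet_table(do.call(rbind, rows))
}

#' Extract triplets from a whole corpus
#'
#' Concatenates [extract_triplets()] results over the sentences in document
#' order, preserving provenance.
#'
#' @param sentences list of `mlr_sentence`.
#' @param ... passed to [extract_triplets()].
#' @return a triplet table with one row per candidate triplet.
#' @export
extract_corpus <- function(sentences, ...) {
  tabs <- lapply(sentences, extract_triplets, ...)
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0L]
  if (length(tabs) == 0L) return(triplet_table())
  triplet_table(do.call(rbind, tabs), stage_label = "extracted")
}
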