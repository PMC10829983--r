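#' Keep triplets that mention at least one domain keyword
#'
#' First refinement stage: a row survives when its subject or object
#' normalised form contains at least one keyword as a substring of one of
#' its whitespace tokens ("asthma" keeps "severe asthma" and "asthma-COPD").
#' Row order is preserved.
#'
#' @param table an `mlr_triplets` table.
#' @param keywords character vector of domain terms (normalised internally).
#' @return the filtered table, stage-labelled `"keyword"`.
#' @export
filter_by_keywords <- function(table, keywords) {
  keywords <- normalize_label(keywords)
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0L) {
    stop("configuration error: keyword set is empty", call. = FALSE)
  }
  hit <- function(phrase) {
    toks <- strsplit(normalize_label(phrase), " ", fixed = TRUE)
    vapply(toks, function(tt) {
      any(vapply(keywords, function(k) any(grepl(k, tt, fixed = TRUE)),
                 logical(1)))
    }, logical(1))
  }
  keep <- hit(table$source) | hit(table$target)
  restage(table[keep, , drop = FALSE], "keyword")
}

#' Keep only complete triplets
#'
#' Second refinement stage: removes candidates with a missing subject,
#' relation or object — a lone entity, a relation with only one entity, or
#' two entities without a relation. Order preserved; idempotent.
#'
#' @param table an `mlr_triplets` table.
#' @return the filtered table, stage-labelled `"complete"`.
#' @export
filter_complete <- function(table) {
  restage(table[table$complete, , drop = FALSE], "complete")
}

#' Eliminate overlapping triplets
#'
#' Third refinement stage: keeps the first occurrence of each normalised
#' (source, edge, target) key — lower case, collapsed whitespace, stripped
#' boundary punctuation — preserving first-occurrence order. Idempotent and
#' key-set preserving.
#'
#' @param table an `mlr_triplets` table.
#' @return the deduplicated table, stage-labelled `"dedup"`.
#' @export
deduplicate <- function(table) {
  keep <- !duplicated(table_keys(table))
  restage(table[keep, , drop = FALSE], "dedup")
}

#' Apply expert-validation decisions
#'
#' Represents the human review stage: rows whose normalised key carries a
#' `rejected` verdict are removed; rows without a decision are kept.
#'
#' @param table an `mlr_triplets` table.
#' @param decisions data frame with columns `source`, `edge`, `target`,
#'   `verdict` (`"approved"` or `"rejected"`) and optionally `reviewer`.
#' @return the filtered table, stage-labelled `"validated"`.
#' @export
apply_validation <- function(table, decisions) {
  decisions <- as.data.frame(decisions, stringsAsFactors = FALSE)
  if (nrow(decisions) == 0L) return(restage(table, "validated"))
  stopifnot(all(c("source", "edge", "target", "verdict") %in% names(decisions)))
  bad <- setdiff(unique(decisions$verdict), c("approved", "rejected"))
  if (length(bad)) {
    stop("validation error: unknown verdict(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dk <- triplet_key(decisions$source, decisions$edge, decisions$target)
  conflict <- tapply(decisions$verdict, dk,
                     function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    keys <- names(conflict)[conflict]
    stop("validation error: conflicting verdicts for key(s): ",
         paste(gsub("\x1f", " | ", keys), collapse = "; "), call. = FALSE)
  }
  rejected <- unique(dk[decisions$verdict == "rejected"])
  keep <- !(table_keys(table) %in% rejected)
  restage(table[keep, , drop = FALSE], "validated")
}

#' Run the staged refinement cascade
#'
#' Applies keyword filtering, completeness filtering and duplicate
#' elimination in that fixed order, optionally followed by validation
#' decisions, and records the row count after each stage. Each stage is
#' non-increasing in rows, so the recorded counts are monotone
#' non-increasing.
#'
#' @param table an extracted `mlr_triplets` table.
#' @param keywords domain keyword vector for [filter_by_keywords()]; `NULL`
#'   skips the keyword stage.
#' @param decisions optional validation decisions for [apply_validation()].
#' @return the refined table; the per-stage row counts are in the
#'   `stage_counts` attribute (named integer vector).
#' @export
refine <- function(table, keywords = NULL, decisions = NULL) {
  counts <- c(extracted = nrow(table))
  out <- table
  if (!is.null(keywords)) {
    out <- filter_by_keywords(out, keywords)
    counts <- c(counts, keyword = nrow(out))
  }
  out <- filter_complete(out)
  counts <- c(counts, complete = nrow(out))
  out <- deduplicate(out)
  counts <- c(counts, dedup = nrow(out))
  if (!is.null(decisions)) {
    out <- apply_validation(out, decisions)
    counts <- c(counts, validated = nrow(out))
  }
  attr(out, "stage_counts") <- counts
  out
}
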