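#' Per-entity subject/object occurrence counts
#'
#' For each distinct normalised entity, counts the distinct triplets where
#' it appears as subject and as object; `overlap` is their sum — the number
#' of triplets the entity participates in (both slots of a self-loop
#' count). Degrees are defined over distinct triplets, so a table that
#' still contains duplicate keys is deduplicated first (with a warning).
#'
#' @param table a deduplicated `mlr_triplets` table of complete rows.
#' @return a tibble with columns `entity`, `subject_count`, `object_count`,
#'   `overlap`, sorted by entity.
#' @export
entity_degrees <- function(table) {
  if (anyDuplicated(table_keys(table))) {
    warning("table contains duplicate triplet keys; deduplicating before ",
            "computing degrees", call. = FALSE)
    table <- deduplicate(table)
  }
  src <- normalize_label(table$source)
  dst <- normalize_label(table$target)
  entities <- sort(unique(c(src, dst)))
  sc <- as.integer(table(factor(src, levels = entities)))
  oc <- as.integer(table(factor(dst, levels = entities)))
  tibble::tibble(entity = entities, subject_count = sc, object_count = oc,
                 overlap = sc + oc)
}

#' Classify entities by triplet overlap
#'
#' Maps each entity's overlap (total triplet participations) to a colour
#' class: 2 participations is `joint2` (orange), 3 or more is `joint3`
#' (purple — the class saturates upward), anything else `default`.
#'
#' @param degrees output of [entity_degrees()].
#' @return named character vector, entity -> class.
#' @export
overlap_classes <- function(degrees) {
  cls <- ifelse(degrees$overlap == 2L, "joint2",
                ifelse(degrees$overlap >= 3L, "joint3", "default"))
  stats::setNames(cls, degrees$entity)
}

#' Enumerate joint constraints at level n
#'
#' The key(a, b) constraints with `max(a, b) = n`, in subject-major order:
#' (n,0), (n,1), ..., (n,n), then (0,n), (1,n), ..., (n-1,n) — `2n + 1`
#' constraints in total (for n = 3 the seven keys (3,0), (3,1), (3,2),
#' (3,3), (0,3), (1,3), (2,3)).
#'
#' @param n constraint level, a positive integer.
#' @return a tibble with columns `subj_required`, `obj_required`.
#' @export
enumerate_constraints <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n)) {
    stop("argument error: n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  tibble::tibble(subj_required = c(rep(n, n + 1L), 0:(n - 1L)),
                 obj_required = c(0:n, rep(n, n)))
}

#' Select joint entities matching a key(a, b) constraint
#'
#' Joint points are entities whose subject and object counts satisfy the
#' constraint. In the default exact mode an entity must have
#' `subject_count == a` and `object_count == b`; with `at_least = TRUE`
#' both counts are lower bounds instead. The result is sorted
#' lexicographically and is a subset of the at-least result for the same
#' key.
#'
#' @param degrees output of [entity_degrees()].
#' @param key the constraint: a length-2 integer vector `c(a, b)` or one
#'   row of [enumerate_constraints()].
#' @param at_least match `>=` instead of `==`?
#' @return character vector of entity labels.
#' @export
find_joints <- function(degrees, key, at_least = FALSE) {
  if (is.data.frame(key)) {
    stopifnot(nrow(key) == 1L)
    key <- c(key$subj_required, key$obj_required)
  }
  stopifnot(length(key) == 2L, all(key >= 0))
  sel <- if (at_least) {
    degrees$subject_count >= key[1] & degrees$object_count >= key[2]
  } else {
    degrees$subject_count == key[1] & degrees$object_count == key[2]
  }
  sort(degrees$entity[sel])
}
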