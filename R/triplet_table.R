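#' Construct a triplet table
#'
#' The unit flowing through every refinement stage: an ordered tibble with
#' character columns `source`, `edge`, `target` and provenance columns
#' `doc_id`, `sent_index`. A `complete` logical column is (re)computed from
#' the three slots — a row is complete iff subject, relation and object are
#' all non-empty after normalisation. The current stage name is stored in
#' the `stage_label` attribute.
#'
#' @param rows a data frame with at least `source`, `edge`, `target`
#'   (provenance columns optional), or `NULL` for an empty table.
#' @param stage_label label stamped on the table for pipeline logging.
#' @return a tibble of class `mlr_triplets`.
#' @export
#' @examples
#' triplet_table(data.frame(source = "severe asthma", edge = "improve",
#'                          target = "SABA alone"))
triplet_table <- function(rows = NULL, stage_label = "raw") {
  if (is.null(rows) || nrow(as.data.frame(rows)) == 0L) {
    rows <- data.frame(source = character(0), edge = character(0),
                       target = character(0), doc_id = character(0),
                       sent_index = integer(0), stringsAsFactors = FALSE)
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("source", "edge", "target")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    stop("triplet table requires column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rows$doc_id)) rows$doc_id <- NA_character_
  if (is.null(rows$sent_index)) rows$sent_index <- NA_integer_
  for (cl in need) rows[[cl]] <- as.character(rows[[cl]])
  rows$complete <- nzchar(normalize_label(rows$source)) &
    nzchar(normalize_label(rows$edge)) &
    nzchar(normalize_label(rows$target))
  out <- tibble::as_tibble(rows[c("source", "edge", "target", "doc_id",
                                  "sent_index", "complete")])
  class(out) <- c("mlr_triplets", class(out))
  attr(out, "stage_label") <- stage_label
  out
}

#' @export
print.mlr_triplets <- function(x, ...) {
  cat("Triplet table [stage: ", stage_label(x), "], ", nrow(x), " row(s), ",
      sum(x$complete), " complete\n", sep = "")
  NextMethod()
}

#' Stage label of a triplet table
#' @param table an `mlr_triplets` table.
#' @return the stage label character scalar.
#' @export
stage_label <- function(table) attr(table, "stage_label") %||% "raw"

restage <- function(table, label) {
  out <- triplet_table(as.data.frame(table), stage_label = label)
  out
}

table_keys <- function(table) {
  triplet_key(table$source, table$edge, table$target)
}
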