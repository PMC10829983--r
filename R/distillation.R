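#' Distill the keyword-centred subgraph
#'
#' Answers a query by pulling the subgraph of all facts touching the
#' keyword: at depth 1, every edge (in either direction) incident to a node
#' matching the keyword, plus those edges' endpoints; at depth d, edges
#' touching any node captured at depth < d (edge-induced hop expansion).
#' Matching is case-insensitive on normalised labels; the default
#' `"substring"` mode lets the query "asthma" capture "severe asthma", the
#' `"exact"` mode requires the whole label to match.
#'
#' The result is a subgraph of the input, monotone in `depth`, and
#' idempotent at equal depth; use [as_triplet_table()] to get it as a
#' table.
#'
#' @param graph an `igraph` knowledge graph built from a deduplicated
#'   table.
#' @param keyword query keyword; must be non-empty after normalisation.
#' @param depth hop count, an integer >= 1 (default 1).
#' @param match_mode `"substring"` (default) or `"exact"`.
#' @return a directed `igraph` subgraph.
#' @export
distill <- function(graph, keyword, depth = 1L,
                    match_mode = c("substring", "exact")) {
  match_mode <- match.arg(match_mode)
  kw <- normalize_label(keyword)
  if (!nzchar(kw)) stop("query error: keyword is empty", call. = FALSE)
  stopifnot(depth >= 1L)
  nm <- igraph::V(graph)$name %||% character(0)
  frontier <- if (match_mode == "substring") {
    which(grepl(kw, nm, fixed = TRUE))
  } else {
    which(nm == kw)
  }
  eids <- integer(0)
  for (d in seq_len(depth)) {
    if (length(frontier) == 0L) break
    inc <- unlist(igraph::incident_edges(graph, frontier, mode = "all"))
    eids <- union(eids, as.integer(inc))
    ends <- igraph::ends(graph, eids, names = FALSE)
    frontier <- union(frontier, unique(as.integer(ends)))
  }
  igraph::subgraph_from_edges(graph, eids, delete.vertices = TRUE)
}
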