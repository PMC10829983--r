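#' Predict query triplets from entity-pair frequency
#'
#' The question-answering front end guesses which facts users will ask
#' about: the `k` most frequent unordered co-occurring entity pairs in the
#' table (ranked by descending pair frequency, ties lexicographic on the
#' normalised pair key) are each turned into a query triplet with the
#' supplied relation, e.g. ("Asthma", "Am", "Asthma"). Subject/object
#' orientation follows the pair's first observed orientation.
#'
#' @param table an `mlr_triplets` table (pre-deduplication frequencies are
#'   what make a pair "common").
#' @param k number of query triplets, a positive integer.
#' @param relation relation label to attach (default `"Am"`).
#' @return a ranked-triplet tibble with columns `source`, `edge`, `target`,
#'   `rank` (1-based, contiguous); fewer than `k` rows if fewer distinct
#'   pairs exist.
#' @export
predict_query_triplets <- function(table, k, relation = "Am") {
  if (length(k) != 1L || is.na(k) || k < 1) {
    stop("argument error: k must be >= 1", call. = FALSE)
  }
  if (nrow(table) == 0L) {
    return(tibble::tibble(source = character(0), edge = character(0),
                          target = character(0), rank = integer(0)))
  }
  src <- normalize_label(table$source)
  dst <- normalize_label(table$target)
  lo <- pmin(src, dst)
  hi <- pmax(src, dst)
  pair_key <- paste(lo, hi, sep = "\x1f")
  tab <- table(pair_key)
  ord <- order(-as.integer(tab), names(tab))
  top <- utils::head(ord, k)
  keys <- names(tab)[top]
  first_at <- match(keys, pair_key)
  tibble::tibble(source = trimws(table$source[first_at]),
                 edge = relation,
                 target = trimws(table$target[first_at]),
                 rank = seq_along(keys))
}

#' Align predicted triplets with the ground truth
#'
#' Intersects a ranked prediction list with a deduplicated ground-truth
#' table on normalised (source, edge, target) keys, keeping only the hits
#' with their original ranks.
#'
#' @param predicted ranked-triplet tibble (columns `source`, `edge`,
#'   `target`, `rank`, optionally `relevance`).
#' @param truth a deduplicated `mlr_triplets` table.
#' @return the hit rows of `predicted`, ranks preserved.
#' @export
align_predictions <- function(predicted, truth) {
  pk <- triplet_key(predicted$source, predicted$edge, predicted$target)
  tk <- unique(table_keys(truth))
  predicted[pk %in% tk, , drop = FALSE]
}

#' Recall, precision and F1 of a prediction list
#'
#' Recall is hits over ground-truth size, precision hits over prediction
#' count, F1 their harmonic mean (0 whenever a denominator is 0).
#'
#' @param hits the aligned hits — a data frame (its row count is used) or a
#'   plain count.
#' @param n_truth ground-truth size.
#' @param n_predicted number of predictions.
#' @return named numeric vector `recall`, `precision`, `f1`.
#' @export
recall_precision_f1 <- function(hits, n_truth, n_predicted) {
  h <- if (is.data.frame(hits)) nrow(hits) else as.numeric(hits)
  stopifnot(n_truth >= 0, n_predicted >= 0, h >= 0)
  recall <- if (n_truth > 0) h / n_truth else 0
  precision <- if (n_predicted > 0) h / n_predicted else 0
  f1 <- if (recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Mean reciprocal rank, ground-truth normalised
#'
#' Sums the reciprocal ranks of the correct answers and divides by the
#' ground-truth size (hits at ranks 1 and 3 over 202 truths give
#' (1 + 1/3)/202). Note the denominator: most of the IR literature divides
#' by the number of queries instead — [mrr_standard()] does that.
#'
#' @param ranks integer vector of hit ranks (1-based).
#' @param n_truth ground-truth size, >= 1.
#' @return MRR value.
#' @export
mrr_paper <- function(ranks, n_truth) {
  if (n_truth < 1) stop("argument error: n_truth must be >= 1", call. = FALSE)
  if (length(ranks) == 0L) return(0)
  stopifnot(all(ranks >= 1))
  sum(1 / ranks) / n_truth
}

#' Mean reciprocal rank, query normalised (standard convention)
#'
#' @param ranks integer vector of hit ranks (1-based).
#' @param n_queries number of queries issued, >= 1.
#' @return standard MRR value.
#' @export
mrr_standard <- function(ranks, n_queries) {
  if (n_queries < 1) stop("argument error: n_queries must be >= 1",
                          call. = FALSE)
  if (length(ranks) == 0L) return(0)
  sum(1 / ranks) / n_queries
}

#' Mean average precision, ground-truth normalised
#'
#' Sums relevance-weighted reciprocal ranks of the correct answers and
#' divides by the ground-truth size: hits at ranks 1 and 3 with grades 1
#' and 2 over 202 truths give (1*1 + 2/3)/202. As with [mrr_paper()], the
#' ground-truth denominator is this pipeline's convention, not the textbook
#' one.
#'
#' @param ranks integer vector of hit ranks (1-based).
#' @param relevance relevance grade per hit (>= 0), recycled if length 1.
#' @param n_truth ground-truth size, >= 1.
#' @return MAP value.
#' @export
map_paper <- function(ranks, relevance = 1, n_truth) {
  if (n_truth < 1) stop("argument error: n_truth must be >= 1", call. = FALSE)
  if (length(ranks) == 0L) return(0)
  stopifnot(all(ranks >= 1), all(relevance >= 0))
  relevance <- rep_len(relevance, length(ranks))
  sum(relevance / ranks) / n_truth
}

#' DCG, ideal DCG and nDCG of a ranked relevance list
#'
#' Discount convention: the gain at rank 1 is undiscounted, the gain at
#' rank i >= 2 is `rel_i / log2(i)` (so binary hits at ranks 1 and 3 give
#' DCG `1 + 1/log2(3)` and, once sorted, IDCG `1 + 1/log2(2) = 2`). The
#' common alternative that discounts every rank by `log2(i + 1)` is
#' selectable. IDCG is the DCG of the descending-sorted list; nDCG their
#' ratio, 0 when IDCG is 0.
#'
#' @param relevances numeric vector of relevance grades by rank (>= 0).
#' @param discount `"log2i"` (default: rank 1 undiscounted, then log2(i))
#'   or `"log2i1"` (log2(i + 1) at every rank).
#' @return named numeric vector `dcg`, `idcg`, `ndcg`.
#' @export
dcg_idcg_ndcg <- function(relevances, discount = c("log2i", "log2i1")) {
  discount <- match.arg(discount)
  stopifnot(all(relevances >= 0))
  dcg_of <- function(rel) {
    if (length(rel) == 0L) return(0)
    i <- seq_along(rel)
    w <- if (discount == "log2i") {
      c(1, 1 / log2(i[-1]))
    } else {
      1 / log2(i + 1)
    }
    sum(rel * w)
  }
  dcg <- dcg_of(relevances)
  idcg <- dcg_of(sort(relevances, decreasing = TRUE))
  ndcg <- if (idcg > 0) dcg / idcg else 0
  c(dcg = dcg, idcg = idcg, ndcg = ndcg)
}

#' Evaluate a prediction list against the ground truth
#'
#' Composes [align_predictions()], [recall_precision_f1()], [mrr_paper()],
#' [map_paper()] and [dcg_idcg_ndcg()] into one report. MAP uses the
#' `relevance` column of `predicted` when present (grades on the hits),
#' else grade 1 per hit; the DCG relevance vector is binary hit/miss over
#' the prediction ranks unless a grade map is wanted there too
#' (`graded_dcg = TRUE` reuses the `relevance` column).
#'
#' @param predicted ranked-triplet tibble.
#' @param truth deduplicated `mlr_triplets` table.
#' @param graded_dcg use the `relevance` column for DCG instead of binary
#'   hits?
#' @param discount DCG discount convention, see [dcg_idcg_ndcg()].
#' @return an object of class `mlr_metrics`: a list with `recall`,
#'   `precision`, `f1`, `mrr`, `map`, `dcg`, `idcg`, `ndcg`, `n_truth`,
#'   `n_predicted`, `n_hits`, `hit_ranks`. Values are unrounded; the print
#'   method shows four decimals (half-up).
#' @export
evaluate <- function(predicted, truth, graded_dcg = FALSE,
                     discount = "log2i") {
  truth <- deduplicate(truth)
  hits <- align_predictions(predicted, truth)
  n_truth <- nrow(truth)
  n_pred <- nrow(predicted)
  rpf <- recall_precision_f1(hits, n_truth, n_pred)
  ranks <- hits$rank
  grades <- if ("relevance" %in% names(hits)) hits$relevance else
    rep(1, length(ranks))
  mrr <- if (n_truth >= 1) mrr_paper(ranks, n_truth) else 0
  map <- if (n_truth >= 1) map_paper(ranks, grades, n_truth) else 0
  rel_by_rank <- numeric(n_pred)
  rel_by_rank[ranks] <- if (graded_dcg) grades else 1
  d <- dcg_idcg_ndcg(rel_by_rank, discount = discount)
  structure(list(recall = unname(rpf["recall"]),
                 precision = unname(rpf["precision"]),
                 f1 = unname(rpf["f1"]),
                 mrr = mrr, map = map,
                 dcg = unname(d["dcg"]), idcg = unname(d["idcg"]),
                 ndcg = unname(d["ndcg"]),
                 n_truth = n_truth, n_predicted = n_pred,
                 n_hits = nrow(hits), hit_ranks = ranks),
            class = "mlr_metrics")
}

#' @export
print.mlr_metrics <- function(x, ...) {
  cat("Query-answering evaluation (", x$n_hits, " hit(s) of ",
      x$n_predicted, " predictions vs ", x$n_truth, " truths)\n", sep = "")
  for (m in c("recall", "precision", "f1", "mrr", "map", "dcg", "idcg",
              "ndcg")) {
    cat(sprintf("  %-9s %.4f\n", m, round_half_up(x[[m]], 4)))
  }
  invisible(x)
}
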