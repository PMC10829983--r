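test_that("predict_query_triplets ranks unordered pairs by frequency", {
  expect_error(predict_query_triplets(triplet_table(), k = 0), "argument error")

  # truncation: k beyond the distinct pairs returns them all
  tab <- mk_table(source = c("A", "B"), edge = "r", target = c("B", "C"))
  expect_identical(nrow(predict_query_triplets(tab, k = 10)), 2L)

  # planted frequencies fix the ranking; orientation is first observed
  fx <- generate_fixture(fixture_config(
    n_sentences = 12, p_incomplete = 0, p_duplicate = 0, keyword_fraction = 0,
    pair_frequency_profile = data.frame(
      source = c("Asthma", "Exacerbation", "Wheezing"),
      target = c("Asthma", "Asthma", "Night"),
      count = c(5, 4, 3)),
    seed = 18))
  pred <- predict_query_triplets(fx$table, k = 2, relation = "Am")
  expect_identical(pred$source, c("Asthma", "Exacerbation"))
  expect_identical(pred$target, c("Asthma", "Asthma"))
  expect_identical(pred$edge, c("Am", "Am"))
  expect_identical(pred$rank, 1:2)

  # the manifest's pair tally is the oracle for the full ordering
  pf <- fx$manifest$pair_frequencies
  pf <- pf[order(-pf$count, pf$source, pf$target), ]
  all_pred <- predict_query_triplets(fx$table, k = nrow(pf))
  lo <- pmin(normalize_label(all_pred$source), normalize_label(all_pred$target))
  hi <- pmax(normalize_label(all_pred$source), normalize_label(all_pred$target))
  expect_identical(paste(lo, hi), paste(pf$source, pf$target))
})

test_that("alignment keeps hit ranks against the deduplicated truth", {
  ps <- paper_scenario()
  hits <- align_predictions(ps$predicted, ps$truth)
  expect_identical(hits$rank, c(1L, 3L))

  disjoint <- tibble::tibble(source = "x", edge = "y", target = "z", rank = 1L)
  expect_identical(nrow(align_predictions(disjoint, ps$truth)), 0L)

  # brute-force set intersection agrees
  brute <- paste(tolower(ps$predicted$source), tolower(ps$predicted$edge),
                 tolower(ps$predicted$target)) %in%
    paste(tolower(ps$truth$source), tolower(ps$truth$edge),
          tolower(ps$truth$target))
  expect_identical(hits$rank, ps$predicted$rank[brute])
})

test_that("recall, precision and F1 use the stated denominators", {
  rpf <- recall_precision_f1(2, n_truth = 202, n_predicted = 10)
  expect_identical(round_half_up(rpf[["recall"]], 4), 0.0099)
  expect_identical(rpf[["precision"]], 0.2)

  expect_identical(recall_precision_f1(0, 202, 10),
                   c(recall = 0, precision = 0, f1 = 0))
  expect_identical(recall_precision_f1(0, 0, 0),
                   c(recall = 0, precision = 0, f1 = 0))

  # oracle: brute-force confusion counts on random prediction sets
  set.seed(42)
  universe <- sprintf("fact%03d", 1:60)
  for (i in 1:10) {
    truth <- sample(universe, 25)
    pred <- sample(universe, 12)
    h <- length(intersect(truth, pred))
    rpf <- recall_precision_f1(h, length(truth), length(pred))
    expect_equal(rpf[["recall"]], h / 25)
    expect_equal(rpf[["precision"]], h / 12)
    if (h > 0) {
      expect_equal(rpf[["f1"]],
                   2 * rpf[["recall"]] * rpf[["precision"]] /
                     (rpf[["recall"]] + rpf[["precision"]]))
    }
  }
})

test_that("MRR and MAP divide by ground-truth size", {
  expect_identical(round_half_up(mrr_paper(c(1, 3), 202), 4), 0.0066)
  expect_identical(mrr_paper(c(1, 3), 202), (1 + 1 / 3) / 202)
  expect_identical(mrr_paper(integer(0), 202), 0)
  expect_identical(mrr_paper(1, 1), 1)
  expect_error(mrr_paper(1, 0), "argument error")

  expect_identical(round_half_up(map_paper(c(1, 3), c(1, 2), 202), 4), 0.0083)
  expect_identical(map_paper(c(1, 3), c(1, 2), 202), (1 + 2 / 3) / 202)
  expect_identical(map_paper(integer(0), numeric(0), 202), 0)

  # with unit relevance MAP collapses to MRR; MRR never exceeds recall
  set.seed(7)
  for (i in 1:20) {
    n_truth <- sample(5:50, 1)
    ranks <- sort(sample(1:20, sample(0:5, 1)))
    expect_equal(map_paper(ranks, 1, n_truth), mrr_paper(ranks, n_truth))
    expect_lte(mrr_paper(ranks, n_truth),
               recall_precision_f1(length(ranks), n_truth, 20)[["recall"]])
  }

  # the standard convention divides by query count instead
  expect_equal(mrr_standard(c(1, 3), 10), (1 + 1 / 3) / 10)
})

test_that("DCG uses the rank-1-undiscounted log2 convention", {
  rel <- c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  d <- dcg_idcg_ndcg(rel)
  expect_equal(d[["dcg"]], 1 + 1 / log2(3))
  expect_identical(d[["idcg"]], 2)
  expect_identical(round_half_up(d[["ndcg"]], 4), 0.8155)

  expect_identical(dcg_idcg_ndcg(rep(0, 5)),
                   c(dcg = 0, idcg = 0, ndcg = 0))

  # an already-ideal ordering scores ndcg 1
  set.seed(11)
  for (i in 1:15) {
    rel <- sort(sample(0:3, 8, replace = TRUE), decreasing = TRUE)
    if (sum(rel) == 0) next
    expect_equal(dcg_idcg_ndcg(rel)[["ndcg"]], 1)
  }

  # binary hits packed at the top are ideal too
  expect_equal(dcg_idcg_ndcg(c(1, 1, 0, 0))[["ndcg"]], 1)

  # the common log2(i+1) convention is selectable and differs
  alt <- dcg_idcg_ndcg(c(1, 0, 1, 0), discount = "log2i1")
  expect_equal(alt[["dcg"]], 1 / log2(2) + 1 / log2(4))
})

test_that("evaluate composes the metrics into one report", {
  ps <- paper_scenario()
  m <- evaluate(ps$predicted, ps$truth)
  expect_s3_class(m, "mlr_metrics")
  expect_identical(m$n_truth, 202L)
  expect_identical(m$n_predicted, 10L)
  expect_identical(m$n_hits, 2L)

  # fields equal the individually computed metrics
  hits <- align_predictions(ps$predicted, ps$truth)
  expect_identical(m$recall,
                   recall_precision_f1(hits, 202, 10)[["recall"]])
  expect_identical(m$mrr, mrr_paper(hits$rank, 202))
  expect_identical(m$map, map_paper(hits$rank, hits$relevance, 202))
  rel <- numeric(10); rel[hits$rank] <- 1
  expect_identical(m$ndcg, dcg_idcg_ndcg(rel)[["ndcg"]])

  # metrics are pure: identical inputs, identical outputs
  expect_identical(unclass(m), unclass(evaluate(ps$predicted, ps$truth)))

  empty <- evaluate(ps$predicted[0, ], ps$truth)
  expect_identical(c(empty$recall, empty$precision, empty$f1, empty$mrr,
                     empty$map, empty$dcg, empty$idcg, empty$ndcg),
                   rep(0, 8))
})
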