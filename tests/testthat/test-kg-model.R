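test_that("build_graph makes one edge per row over normalised nodes", {
  g0 <- build_graph(triplet_table())
  expect_identical(igraph::ecount(g0), 0)

  tab <- example_triplets()
  g <- build_graph(tab)
  expect_identical(igraph::ecount(g), 16)
  expect_true(igraph::is_directed(g))
  # edge multiset equals the table's rows
  expect_identical(sort(igraph::edge_attr(g, "relation")), sort(tab$edge))
  expect_identical(as_triplet_table(g)$source, trimws(tab$source))

  # incomplete rows are a contract violation, named by row index
  bad <- mk_table(source = c("A", ""), edge = c("r", "r"),
                  target = c("B", "C"))
  expect_error(build_graph(bad), "row.* 2")

  # parallel edges survive (multigraph, not simple graph)
  dup <- mk_table(source = c("a", "a"), edge = c("r", "r"),
                  target = c("b", "b"))
  expect_identical(igraph::ecount(build_graph(dup)), 2)

  # structural bound: nodes never exceed twice the edges
  fx <- generate_fixture(fixture_config(n_sentences = 80, seed = 12))
  gf <- build_graph(filter_complete(fx$table))
  expect_lte(igraph::vcount(gf), 2 * igraph::ecount(gf))
})

test_that("top_relations ranks by frequency with lexicographic ties", {
  expect_identical(nrow(top_relations(triplet_table())), 0L)
  expect_error(top_relations(triplet_table(), k = 0), "argument error")

  tab <- mk_table(source = letters[1:9], edge = rep(c("c", "a", "b"), c(5, 3, 1)),
                  target = LETTERS[1:9])
  tr <- top_relations(tab, k = 2)
  expect_identical(tr$relation, c("c", "a"))
  expect_identical(tr$count, c(5L, 3L))

  # ties break lexicographically ascending
  tied <- mk_table(source = letters[1:4], edge = c("z", "y", "y", "z"),
                   target = LETTERS[1:4])
  expect_identical(top_relations(tied, 2)$relation, c("y", "z"))

  # surface forms stay distinct and the counts are conserved
  tr16 <- top_relations(example_triplets(), k = 20)
  expect_true(all(c("include", "included") %in% tr16$relation))
  expect_identical(sum(tr16$count), 16L)
})

test_that("relation sub-KGs partition the edge multiset", {
  tab <- filter_complete(generate_fixture(
    fixture_config(n_sentences = 60, seed = 13))$table)
  g <- build_graph(tab)

  expect_identical(igraph::ecount(sub_kg_by_relation(g, "no such relation")), 0)

  rels <- unique(igraph::edge_attr(g, "relation"))
  per_rel <- lapply(rels, function(r) sub_kg_by_relation(g, r))
  expect_identical(sum(vapply(per_rel, igraph::ecount, numeric(1))),
                   igraph::ecount(g))
  # every sub-KG carries only its own relation
  for (i in seq_along(rels)) {
    expect_true(all(igraph::edge_attr(per_rel[[i]], "relation") == rels[i]))
  }
})

test_that("CSV round-trip is lossless in the Source,Edge,Target dialect", {
  f <- withr::local_tempfile(fileext = ".csv")

  tab <- example_triplets()
  write_table(tab, f)
  expect_identical(readLines(f, n = 1), "\"Source\",\"Edge\",\"Target\"")
  back <- read_table(f)
  expect_identical(back$source, tab$source)
  expect_identical(back$edge, tab$edge)
  expect_identical(back$target, tab$target)

  write_table(triplet_table(), f)
  expect_identical(nrow(read_table(f)), 0L)

  # commas and quotes in phrases survive RFC-4180 quoting
  tricky <- mk_table(source = c('He said "stop"', "a, b, and c"),
                     edge = c("says, loudly", "lists"),
                     target = c("x,y", '"quoted"'))
  write_table(tricky, f)
  back2 <- read_table(f)
  expect_identical(back2$source, tricky$source)
  expect_identical(back2$edge, tricky$edge)
  expect_identical(back2$target, tricky$target)

  writeLines(c("Wrong,Header,Here", "a,b,c"), f)
  expect_error(read_table(f), "format error")
})

test_that("interactive export embeds every node and edge exactly once", {
  f <- withr::local_tempfile(fileext = ".html")

  g0 <- build_graph(triplet_table())
  export_interactive(g0, path = f)
  html <- readLines(f)
  payload <- jsonlite::fromJSON(html[grep("application.json", html) + 1])
  expect_length(payload$nodes, 0)

  tab <- mk_table(source = c("a", "a", "c", "d"), edge = "r",
                  target = c("b", "c", "d", "e"))
  g <- build_graph(tab)
  cls <- c(a = "joint2", b = "joint2", e = "joint3")
  export_interactive(g, colors = cls, path = f)
  html <- readLines(f)
  payload <- jsonlite::fromJSON(html[grep("application.json", html) + 1])
  expect_identical(sort(payload$nodes$id), c("a", "b", "c", "d", "e"))
  expect_identical(nrow(payload$edges), 4L)
  expect_identical(sum(payload$nodes$class == "joint2"), 2L)
  # colour classes follow the palette: joint2 orange, joint3 purple
  expect_identical(payload$nodes$color[payload$nodes$id == "a"],
                   unname(kg_palette()["joint2"]))
  expect_identical(payload$nodes$color[payload$nodes$id == "e"],
                   unname(kg_palette()["joint3"]))
  expect_identical(payload$nodes$color[payload$nodes$id == "c"],
                   unname(kg_palette()["default"]))

  expect_error(export_interactive(g, colors = c(a = "magenta"), path = f))
})
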