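test_that("parse_interactions splits fields and deduplicates sources", {
  f <- withr::local_tempfile()
  writeLines(c("EGFR\tGRB2\tbinds\tHPRD;IntAct",
               "TP53\tTP53\tcomplex\tReactome",
               "A\tB\tx\tHPRD;HPRD"), f)
  rec <- parse_interactions(f)
  expect_equal(nrow(rec), 3L)
  expect_setequal(rec$sources[[1]], c("HPRD", "IntAct"))
  # self-pair retained at parse stage, pruned only in build_network
  expect_identical(rec$gene_a[2], rec$gene_b[2])
  expect_identical(rec$sources[[3]], "HPRD")
})

test_that("parse_interactions flags malformed lines and empty files", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\tpp\tS1", "CJUST_ONE_FIELD"), f)
  expect_error(parse_interactions(f), "line 2")
  writeLines(character(0), f)
  expect_warning(rec <- parse_interactions(f), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("build_network filters by the union of distinct sources per pair", {
  recs <- make_records(list(
    list("A", "B", "pp", "S1"),
    list("A", "B", "pp", "S2"),
    list("B", "C", "pp", "S1"),
    list("C", "C", "pp", c("S1", "S2"))))
  g2 <- build_network(recs, min_sources = 2)
  expect_equal(igraph::ecount(g2), 1L)
  expect_true(igraph::are_adjacent(g2, "A", "B"))
  g1 <- build_network(recs, min_sources = 1)
  expect_equal(igraph::ecount(g1), 2L)
  # the same single source seen twice is still one source
  dup <- make_records(list(
    list("A", "B", "pp", "S1"),
    list("A", "B", "pp", "S1")))
  expect_warning(g0 <- build_network(dup, min_sources = 2), "no gene pair")
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("build_network output is always simple, for random record lists", {
  set.seed(71)
  pool <- LETTERS[1:8]
  srcs <- paste0("S", 1:4)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    recs <- make_records(lapply(seq_len(n), function(.) {
      list(sample(pool, 1), sample(pool, 1), "pp",
           sample(srcs, sample(1:3, 1)))
    }))
    k <- sample(1:3, 1)
    g <- suppressWarnings(build_network(recs, min_sources = k))
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
    # monotone filtering: raising the threshold only removes edges
    g_next <- suppressWarnings(build_network(recs, min_sources = k + 1L))
    el <- function(x) apply(igraph::as_edgelist(x), 1,
                            function(e) paste(sort(e), collapse = "|"))
    expect_true(all(el(g_next) %in% el(g)))
  }
})

test_that("largest_component keeps the biggest piece with a deterministic tie-break", {
  g <- toy_graph("a","b", "b","c", "c","d", "d","e", "x","y")
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a","b","c","d","e"))
  # connected graph is returned whole
  tri <- toy_graph("a","b", "b","c", "c","a")
  expect_equal(igraph::vcount(largest_component(tri)), 3L)
  # size tie: component containing the lexicographically smallest node wins
  tie <- toy_graph("ZZ1","ZZ2", "ZZ2","ZZ3", "AAA","BBB", "BBB","CCC")
  expect_true("AAA" %in% igraph::V(largest_component(tie))$name)
  expect_error(largest_component(igraph::make_empty_graph(0)), "empty")
})

test_that("degree_histogram counts nodes per degree consistently", {
  star <- toy_graph("c","l1", "c","l2", "c","l3", "c","l4")
  h <- degree_histogram(star)
  expect_equal(h[order(h$degree), ],
               data.frame(degree = c(1L, 4L), count = c(4L, 1L)),
               ignore_attr = TRUE)
  tri <- toy_graph("a","b", "b","c", "c","a")
  expect_equal(degree_histogram(tri), data.frame(degree = 2L, count = 3L))
  p4 <- toy_graph("a","b", "b","c", "c","d")
  h4 <- degree_histogram(p4)
  expect_equal(h4[order(h4$degree), ]$count, c(2L, 2L))
  # sum of counts = |V|, sum of degree*count = 2|E|
  set.seed(3)
  g <- random_connected_graph(40)
  h <- degree_histogram(g)
  expect_equal(sum(h$count), igraph::vcount(g))
  expect_equal(sum(h$degree * h$count), 2L * igraph::ecount(g))
})

test_that("SIF round-trips the edge set", {
  recs <- make_records(list(
    list("A", "B", "binds", c("S1", "S2")),
    list("B", "C", "activates", c("S1", "S3"))))
  g <- build_network(recs)
  f <- withr::local_tempfile()
  write_sif(g, f)
  back <- read_sif(f)
  el <- function(x) sort(apply(igraph::as_edgelist(x), 1,
                               function(e) paste(sort(e), collapse = "|")))
  expect_identical(el(back), el(g))
  expect_setequal(igraph::E(back)$interaction_type, c("binds", "activates"))
})
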