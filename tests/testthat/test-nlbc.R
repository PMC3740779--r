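test_that("bfs_shortest_paths satisfies the shortest-path DAG invariants", {
  cyc <- toy_graph("A","B", "B","C", "C","D", "D","A")
  sp <- bfs_shortest_paths(cyc, "A")
  expect_equal(sp$dist[["C"]], 2L)
  expect_equal(sp$sigma[["C"]], 2)
  expect_setequal(sp$preds[["C"]], c("B", "D"))
  p3 <- toy_graph("A","B", "B","C")
  sp3 <- bfs_shortest_paths(p3, "A")
  expect_equal(sp3$sigma[["C"]], 1)
  expect_equal(sp3$dist[["C"]], 2L)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("a","b","c","d")
  spk <- bfs_shortest_paths(k4, "a")
  expect_true(all(spk$dist[c("b","c","d")] == 1L))
  expect_true(all(spk$sigma[c("b","c","d")] == 1))
  expect_error(bfs_shortest_paths(p3, "ZZZ"), "ZZZ")

  # property: sigma(u) = sum over preds of sigma(p), dist(p) = dist(u) - 1
  set.seed(42)
  for (i in 1:10) {
    g <- random_connected_graph(sample(8:25, 1))
    s <- sample(igraph::V(g)$name, 1)
    sp <- bfs_shortest_paths(g, s)
    expect_equal(sp$dist[[s]], 0L)
    expect_equal(sp$sigma[[s]], 1)
    expect_length(sp$preds[[s]], 0L)
    for (u in setdiff(names(sp$dist), s)) {
      expect_equal(sp$sigma[[u]], sum(sp$sigma[sp$preds[[u]]]))
      expect_true(all(sp$dist[sp$preds[[u]]] == sp$dist[[u]] - 1L))
    }
  }
})

test_that("compute_nlbc reproduces the analytic toy geometries exactly", {
  # single path: the interior node carries every shortest path
  p3 <- toy_graph("s","v", "v","t")
  ct <- compute_nlbc(p3, map_input_genes(p3, c("s","t")))
  expect_equal(ct$values[["v"]], 1.0)
  expect_equal(ct$values[["s"]], 0.0)

  # diamond: two symmetric shortest paths split the credit
  dia <- toy_graph("s","a", "a","t", "s","b", "b","t")
  ctd <- compute_nlbc(dia, map_input_genes(dia, c("s","t")))
  expect_equal(ctd$values[["a"]], 0.5)
  expect_equal(ctd$values[["b"]], 0.5)

  # asymmetric weighted bridge
  br <- toy_graph("s1","b1", "b1","t", "s2","b2", "b2","t")
  inp <- map_input_genes(br, c("s1","s2","t"), weights = c(2, 1, 1))
  ctb <- compute_nlbc(br, inp)
  expect_equal(ctb$normalizer, 8)
  expect_equal(ctb$values[["b1"]], 0.75)
  expect_equal(ctb$values[["b2"]], 0.625)
  expect_equal(ctb$values[["t"]], 0.375)
  expect_equal(ctb$values[["s1"]], 0)
  expect_equal(ctb$values[["s2"]], 0)

  # adjacent input pair: no interior node exists anywhere
  adj2 <- toy_graph("s","t", "t","x")
  cta <- compute_nlbc(adj2, map_input_genes(adj2, c("s","t")))
  expect_true(all(cta$values == 0))
})

test_that("compute_nlbc rejects degenerate inputs", {
  p3 <- toy_graph("s","v", "v","t")
  expect_error(map_input_genes(p3, "s"), "fewer than 2")
  expect_error(map_input_genes(p3, c("s","t"), weights = c(1, -1)),
               "strictly positive")
  expect_warning(inp <- map_input_genes(p3, c("s","t","NOPE")), "dropped")
  expect_identical(inp$dropped, "NOPE")
})

test_that("brute-force enumeration agrees with the Brandes accumulation", {
  set.seed(1234)
  for (i in 1:40) {
    g <- random_connected_graph(sample(6:30, 1))
    inp <- random_inputs(g, sample(2:min(8, igraph::vcount(g)), 1))
    fast <- compute_nlbc(g, inp)
    slow <- brute_force_nlbc(g, inp)
    expect_equal(fast$values, slow$values, tolerance = 1e-12)
    expect_equal(fast$normalizer, slow$normalizer)
    expect_true(all(fast$values >= 0 & fast$values <= 1 + 1e-12))
  }
  big <- random_connected_graph(250)
  expect_error(brute_force_nlbc(big, random_inputs(big, 3)), "oracle")
})

test_that("nlBC handles disconnected input pairs as zero-path contributions", {
  g <- toy_graph("s","v", "v","t", "x","y")
  inp <- map_input_genes(g, c("s", "t", "x"))
  ct <- compute_nlbc(g, inp)
  bf <- brute_force_nlbc(g, inp)
  # pair weights of disconnected pairs still inflate the normalizer:
  # only the s-t pair routes through v, so nlBC(v) = 2/6
  expect_equal(ct$values[["v"]], 2 / 6)
  expect_equal(ct$values, bf$values, tolerance = 1e-12)
})

test_that("nlBC is invariant to rescaling all weights", {
  set.seed(99)
  g <- random_connected_graph(20)
  u <- sample(igraph::V(g)$name, 5)
  w <- runif(5, 0.5, 3)
  a <- compute_nlbc(g, map_input_genes(g, u, w))
  b <- compute_nlbc(g, map_input_genes(g, u, w * 137.5))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("uniform weights reduce nlBC to the pair-averaged restricted betweenness", {
  set.seed(7)
  for (i in 1:5) {
    g <- random_connected_graph(15)
    u <- sample(igraph::V(g)$name, 4)
    ct <- compute_nlbc(g, map_input_genes(g, u))
    expect_equal(ct$values, igraph_pair_average(g, u), tolerance = 1e-10)
  }
})

test_that("with U = V and uniform weights nlBC reduces to scaled classical betweenness", {
  set.seed(11)
  g <- random_connected_graph(18)
  nm <- igraph::V(g)$name
  ct <- compute_nlbc(g, map_input_genes(g, nm))
  bc <- standard_bc(g)
  expect_equal(ct$values, bc / choose(length(nm), 2), tolerance = 1e-10)
})

test_that("standard_bc matches the closed forms", {
  p3 <- toy_graph("A","B", "B","C")
  bc <- standard_bc(p3)
  expect_equal(bc[["B"]], 1)
  expect_equal(bc[["A"]], 0)
  star <- toy_graph("c","l1", "c","l2", "c","l3", "c","l4", "c","l5")
  expect_equal(standard_bc(star)[["c"]], choose(5, 2))
  cyc <- toy_graph("A","B", "B","C", "C","D", "D","A")
  expect_true(all(abs(standard_bc(cyc) - 0.5) < 1e-12))
})

test_that("inflating one input weight approaches the single-source dependency limit", {
  set.seed(21)
  g <- random_connected_graph(16)
  u <- sample(igraph::V(g)$name, 5)
  s <- u[1]
  inp <- map_input_genes(g, u, weights = c(1e6, rep(1, 4)))
  ct <- compute_nlbc(g, inp)
  # limit: average over t != s of sigma_st(v)/sigma_st
  nm <- igraph::V(g)$name
  lim <- stats::setNames(numeric(length(nm)), nm)
  for (t in u[-1]) {
    ps <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
    for (p in ps) {
      interior <- setdiff(names(p), c(s, t))
      lim[interior] <- lim[interior] + 1 / length(ps)
    }
  }
  lim <- lim / (length(u) - 1)
  expect_equal(ct$values, lim, tolerance = 1e-4)
})
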