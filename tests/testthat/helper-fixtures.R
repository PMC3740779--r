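# Shared builders for toy graphs, record lists and random instances.

# Named undirected graph from an even-length vector of endpoint symbols.
toy_graph <- function(...) {
  ends <- c(...)
  igraph::graph_from_edgelist(matrix(ends, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

# Interaction records from a list of list(a, b, type, sources) entries.
make_records <- function(entries) {
  interaction_records(
    vapply(entries, `[[`, character(1), 1L),
    vapply(entries, `[[`, character(1), 2L),
    vapply(entries, `[[`, character(1), 3L),
    lapply(entries, `[[`, 4L))
}

# Random connected named graph on n nodes (Erdos-Renyi, resampled until
# connected); used by the oracle-equivalence and property tests. The
# density stays above the ~log(n)/n connectivity threshold so the
# resampling loop terminates quickly.
random_connected_graph <- function(n, p = min(1, max(2.5, 1.3 * log(n)) / n)) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# Random input gene set: k distinct nodes, weights uniform in (0.1, 5].
random_inputs <- function(net, k) {
  nm <- igraph::V(net)$name
  map_input_genes(net, sample(nm, k), weights = stats::runif(k, 0.1, 5))
}

# Pair-averaged restricted betweenness computed independently through
# igraph's shortest-path enumeration: for uniform weights,
# nlBC(v) = mean over input pairs of sigma_st(v)/sigma_st.
igraph_pair_average <- function(net, u) {
  nm <- igraph::V(net)$name
  acc <- stats::setNames(numeric(length(nm)), nm)
  pairs <- utils::combn(u, 2)
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    ps <- igraph::all_shortest_paths(net, from = s, to = t)$vpaths
    if (length(ps) == 0L) next
    for (p in ps) {
      interior <- setdiff(names(p), c(s, t))
      acc[interior] <- acc[interior] + 1 / length(ps)
    }
  }
  acc / ncol(pairs)
}
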