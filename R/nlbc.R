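#' Breadth-first shortest-path structure from one source
#'
#' Computes, for an unweighted undirected network, the hop distance,
#' the number of distinct shortest paths `sigma`, and the shortest-path
#' predecessor lists from a single source node. This is the DAG that
#' both the centrality accumulation and the subgraph extraction walk.
#'
#' @param net Background network (igraph).
#' @param source Gene symbol of the source node.
#' @return A list with `source`, and named vectors/lists over the nodes
#'   reachable from the source: `dist` (integer hop counts), `sigma`
#'   (shortest-path counts) and `preds` (character vectors of
#'   shortest-path predecessors; empty for the source).
#' @export
bfs_shortest_paths <- function(net, source) {
  stopifnot(igraph::is_igraph(net))
  nm <- igraph::V(net)$name
  s <- match(source, nm)
  if (is.na(s)) stop("source node not in network: ", source)
  n <- length(nm)
  adj <- igraph::as_adj_list(net, mode = "all")
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (v in as.integer(adj[[u]])) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        tail <- tail + 1L
        queue[tail] <- v
      }
      if (dist[v] == dist[u] + 1L) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  reach <- which(!is.na(dist))
  list(source = source,
       dist = stats::setNames(dist[reach], nm[reach]),
       sigma = stats::setNames(sigma[reach], nm[reach]),
       preds = stats::setNames(
         lapply(preds[reach], function(p) nm[p]), nm[reach]))
}

# Internal: igraph -> 0-based CSR (ptr, adj) for the C++ core.
as_csr <- function(net) {
  n <- igraph::vcount(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  lens <- lengths(adj)
  list(ptr = c(0L, cumsum(lens)),
       adj = as.integer(unlist(adj, use.names = FALSE)) - 1L,
       n = n)
}

new_centrality_table <- function(values, normalizer) {
  structure(list(values = values,
                 normalizer = normalizer,
                 pair_convention = "unordered"),
            class = "centrality_table")
}

#' @export
print.centrality_table <- function(x, ...) {
  nz <- sum(x$values > 0)
  cat("Node-limited betweenness centrality over ", length(x$values),
      " node(s); ", nz, " nonzero; normalizer w = ",
      format(x$normalizer), "\n", sep = "")
  invisible(x)
}

#' Node-limited betweenness centrality
#'
#' Computes, for every node `v` of the network, the centrality
#' \deqn{nlBC(v) = \frac{1}{w} \sum_{\{s,t\} \subseteq U, s \ne t}
#'   (w(s)+w(t)) \frac{\sigma_{st}(v)}{\sigma_{st}},\qquad
#'   w = \sum_{\{s,t\}} (w(s)+w(t)),}
#' where the sum runs over unordered pairs of distinct input nodes,
#' \eqn{\sigma_{st}} counts shortest paths between `s` and `t`, and
#' \eqn{\sigma_{st}(v)} those passing through `v` as an *interior* node
#' (`v` distinct from both endpoints, the classical betweenness
#' convention). Values lie in `[0, 1]`; scaling all weights by a common
#' factor leaves them unchanged. Implemented as one Brandes-style
#' backward accumulation per input source carrying an unweighted and a
#' target-weighted dependency, in C++.
#'
#' A pair of input nodes with no connecting path contributes 0 to the
#' numerator while its weight term is still counted in the normalizer.
#'
#' @param net Background network (igraph).
#' @param inputs An `input_gene_set` from [map_input_genes()].
#' @return A `centrality_table`: list with `values` (named numeric over
#'   all network nodes), `normalizer` (the unordered-pair weight sum `w`)
#'   and `pair_convention`.
#' @seealso [brute_force_nlbc()] for the enumeration oracle,
#'   [simulate_null()] for significance.
#' @export
compute_nlbc <- function(net, inputs) {
  check_inputs(net, inputs)
  nm <- igraph::V(net)$name
  csr <- as_csr(net)
  src <- match(names(inputs$weights), nm) - 1L
  vals <- .nlbc_brandes_csr(csr$ptr, csr$adj, src,
                            as.numeric(inputs$weights), csr$n)
  m <- length(inputs$weights)
  new_centrality_table(stats::setNames(vals, nm),
                       (m - 1) * sum(inputs$weights))
}

#' Brute-force nlBC by shortest-path enumeration
#'
#' Independent oracle for [compute_nlbc()]: enumerates every shortest
#' path between every unordered pair of input nodes by recursing over
#' the BFS predecessor DAG, and accumulates the defining sum literally.
#' Intended for small test networks only.
#'
#' @inheritParams compute_nlbc
#' @param max_nodes Size guard; networks larger than this are refused.
#' @return A `centrality_table` with the same contract as
#'   [compute_nlbc()].
#' @export
brute_force_nlbc <- function(net, inputs, max_nodes = 200L) {
  check_inputs(net, inputs)
  if (igraph::vcount(net) > max_nodes) {
    stop("brute_force_nlbc is a test oracle; network exceeds ", max_nodes, " nodes")
  }
  nm <- igraph::V(net)$name
  w <- inputs$weights
  u <- names(w)
  acc <- stats::setNames(numeric(length(nm)), nm)
  enumerate_paths <- function(preds, t) {
    if (length(preds[[t]]) == 0L) return(list(t))
    out <- list()
    for (p in preds[[t]]) {
      for (tail in enumerate_paths(preds, p)) out[[length(out) + 1L]] <- c(tail, t)
    }
    out
  }
  for (i in seq_len(length(u) - 1L)) {
    sp <- bfs_shortest_paths(net, u[i])
    for (j in (i + 1L):length(u)) {
      t <- u[j]
      if (!t %in% names(sp$dist)) next  # disconnected pair: 0 paths
      paths <- enumerate_paths(sp$preds, t)
      pair_w <- w[i] + w[j]
      for (p in paths) {
        interior <- setdiff(p, c(u[i], t))
        acc[interior] <- acc[interior] + pair_w / length(paths)
      }
    }
  }
  m <- length(u)
  norm <- (m - 1) * sum(w)
  new_centrality_table(acc / norm, norm)
}

#' Classical betweenness centrality
#'
#' Unnormalized betweenness over unordered pairs of all nodes,
#' \eqn{BC(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}}. Used
#' as the global-limit cross-check: with `U` equal to all nodes and
#' uniform weights, nlBC reduces to `BC / choose(|V|, 2)`.
#'
#' @param net Background network (igraph).
#' @return Named numeric vector of betweenness values.
#' @export
standard_bc <- function(net) {
  stopifnot(igraph::is_igraph(net))
  bc <- igraph::betweenness(net, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(bc), igraph::V(net)$name)
}
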