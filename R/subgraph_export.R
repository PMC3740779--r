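#' Extract the shortest-path-union subgraph connecting the input genes
#'
#' Builds the subgraph `H` whose nodes and edges lie on at least one
#' shortest path between some unordered pair of distinct input nodes —
#' the only nodes eligible for nonzero nlBC, plus the input endpoints
#' themselves, which anchor the paths. Computed by one BFS per input
#' source followed by a backward walk over the shortest-path predecessor
#' DAG from every reachable input target. `H` does not depend on the
#' input weights (weights change centrality values, not which paths are
#' shortest).
#'
#' @param net Background network (igraph).
#' @param inputs An `input_gene_set` from [map_input_genes()].
#' @return An igraph subgraph of `net` (edge attributes preserved).
#' @export
extract_subgraph <- function(net, inputs) {
  check_inputs(net, inputs)
  nm <- igraph::V(net)$name
  u <- names(inputs$weights)
  edge_keys <- character(0)
  edge_a <- character(0)
  edge_b <- character(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in u) {
    sp <- bfs_shortest_paths(net, s)
    targets <- intersect(setdiff(u, s), names(sp$dist))
    if (length(targets) == 0L) next
    # Backward cone: every node reachable from a target via predecessor
    # links sits on some shortest s-t path; each (pred, node) link is an
    # edge of H.
    visited <- new.env(hash = TRUE, parent = emptyenv())
    stack <- targets
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.null(visited[[v]])) next
      visited[[v]] <- TRUE
      for (p in sp$preds[[v]]) {
        key <- if (p < v) paste(p, v, sep = "\r") else paste(v, p, sep = "\r")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          edge_a <- c(edge_a, p)
          edge_b <- c(edge_b, v)
        }
        if (is.null(visited[[p]])) stack <- c(stack, p)
      }
    }
  }
  if (length(edge_a) == 0L) {
    stop("no input pair is connected; the extracted subgraph is empty")
  }
  eids <- igraph::get_edge_ids(net, rbind(edge_a, edge_b))
  igraph::subgraph_from_edges(net, eids, delete.vertices = TRUE)
}

#' Export a subgraph and results for Cytoscape
#'
#' Writes the extracted subgraph as a SIF file plus plain-text node
#' attribute (`.noa`) files in the Cytoscape 2.x format (a header line
#' with the attribute name, then `node = value` lines):
#' \describe{
#'   \item{`<prefix>.sif`}{one `geneA type geneB` line per edge of H;
#'     type defaults to `"pp"` when the provenance lacks one.}
#'   \item{`<prefix>.pvalue.noa`}{simulated p-value per node (1.0 for
#'     nodes absent from the result table, e.g. zero-centrality
#'     endpoints), for colour-depth rendering.}
#'   \item{`<prefix>.inweight.noa`}{input weight per node, 0 for
#'     non-input nodes — encodes both membership and weight, for border
#'     rendering.}
#'   \item{`<prefix>.nlbc.noa`}{observed nlBC per node.}
#' }
#'
#' @param sub Extracted subgraph from [extract_subgraph()].
#' @param results Result table from [build_result_table()]; nodes of the
#'   subgraph missing from it default to p-value 1 and nlBC 0 unless
#'   `centrality` is given.
#' @param inputs The `input_gene_set`.
#' @param prefix Output path prefix.
#' @param centrality Optional `centrality_table` supplying nlBC values
#'   for nodes filtered out of `results`.
#' @return Character vector of the four file paths, invisibly.
#' @export
export_cytoscape <- function(sub, results, inputs, prefix, centrality = NULL) {
  stopifnot(igraph::is_igraph(sub))
  if (igraph::vcount(sub) == 0L) stop("empty subgraph; nothing to visualize")
  nodes <- igraph::V(sub)$name

  sif <- paste0(prefix, ".sif")
  write_sif(sub, sif)

  pv <- stats::setNames(rep(1.0, length(nodes)), nodes)
  nl <- stats::setNames(rep(0.0, length(nodes)), nodes)
  hit <- intersect(results$gene, nodes)
  pv[hit] <- results$p_value[match(hit, results$gene)]
  nl[hit] <- results$nlBC[match(hit, results$gene)]
  if (!is.null(centrality)) {
    stopifnot(inherits(centrality, "centrality_table"))
    known <- intersect(names(centrality$values), nodes)
    nl[known] <- centrality$values[known]
  }
  iw <- stats::setNames(rep(0.0, length(nodes)), nodes)
  on_input <- intersect(names(inputs$weights), nodes)
  iw[on_input] <- inputs$weights[on_input]

  write_noa <- function(values, attr_name, path) {
    writeLines(c(attr_name, paste(names(values), "=", values)), path)
    path
  }
  paths <- c(sif,
             write_noa(pv, "SimulatedPValue", paste0(prefix, ".pvalue.noa")),
             write_noa(iw, "InputWeight", paste0(prefix, ".inweight.noa")),
             write_noa(nl, "nlBC", paste0(prefix, ".nlbc.noa")))
  invisible(paths)
}
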