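#' Parse a multi-source molecular interaction table
#'
#' Reads a tab-separated interaction file in the style of a Pathway
#' Commons binary-interaction export: one interaction per line with
#' columns `geneA`, `geneB`, `interaction type` and a delimited list of
#' the source databases that report the interaction. No merging happens
#' here; lines are returned one record each (collapsing of redundant
#' records into edges is the job of [build_network()]).
#'
#' @param path Path to the interaction file.
#' @param source_delim Delimiter separating source-database names inside
#'   the fourth column (default `";"`).
#' @param comment_char Lines starting with this character are skipped.
#' @return A data frame of interaction records with columns `gene_a`,
#'   `gene_b`, `interaction_type` and a list-column `sources` holding the
#'   deduplicated character vector of source names for each record.
#' @examples
#' f <- tempfile()
#' writeLines("EGFR\tGRB2\tbinds\tHPRD;IntAct", f)
#' parse_interactions(f)
#' @export
parse_interactions <- function(path, source_delim = ";", comment_char = "#") {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment_char)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty interaction file: ", path)
    return(interaction_records(character(), character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("malformed interaction line ", bad, ": fewer than 3 tab-separated fields")
  }
  gene_a <- vapply(fields, `[[`, character(1), 1L)
  gene_b <- vapply(fields, `[[`, character(1), 2L)
  type <- vapply(fields, `[[`, character(1), 3L)
  src_raw <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", character(1))
  sources <- lapply(strsplit(src_raw, source_delim, fixed = TRUE), function(s) {
    unique(trimws(s[nzchar(trimws(s))]))
  })
  if (any(!nzchar(gene_a)) || any(!nzchar(gene_b))) {
    stop("empty gene symbol in interaction file")
  }
  interaction_records(gene_a, gene_b, type, sources)
}

#' Construct interaction records from vectors
#'
#' Low-level constructor used by [parse_interactions()] and the synthetic
#' fixture generator. Source lists are deduplicated per record.
#'
#' @param gene_a,gene_b Character vectors of gene symbols.
#' @param interaction_type Character vector of free-text interaction labels.
#' @param sources List of character vectors of source-database names.
#' @return A data frame of interaction records (see [parse_interactions()]).
#' @export
interaction_records <- function(gene_a, gene_b, interaction_type, sources) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(interaction_type),
            length(gene_a) == length(sources))
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   interaction_type = as.character(interaction_type),
                   stringsAsFactors = FALSE)
  df$sources <- lapply(sources, function(s) unique(as.character(s)))
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Build the background biomolecular network
#'
#' Collapses interaction records into a simple, undirected, unweighted
#' graph. For each unordered gene pair the union of source databases
#' across all records is formed; the pair becomes an edge iff the union
#' holds at least `min_sources` distinct sources. Self-pairs are pruned
#' and multi-records collapse to single edges, so the result has no
#' self-loops and no multi-edges. Requiring support from two or more
#' independent databases is what restores a clean power-law degree
#' distribution in aggregated pathway resources.
#'
#' @param records Interaction records from [parse_interactions()].
#' @param min_sources Minimum number of distinct supporting source
#'   databases for a pair to become an edge (default 2).
#' @return An [igraph::igraph] object with vertex attribute `name` and
#'   edge attributes `n_sources` (distinct source count), `sources`
#'   (collapsed `;`-separated names) and `interaction_type` (collapsed
#'   `|`-separated distinct types seen for the pair).
#' @export
build_network <- function(records, min_sources = 2L) {
  stopifnot(is.data.frame(records), min_sources >= 1L)
  if (nrow(records) == 0L) {
    warning("no interaction records; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  a <- records$gene_a
  b <- records$gene_b
  self <- a == b
  a <- a[!self]; b <- b[!self]
  srcs <- records$sources[!self]
  types <- records$interaction_type[!self]
  if (length(a) == 0L) {
    warning("only self-interactions present; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  idx <- split(seq_along(key), key)
  src_union <- lapply(idx, function(i) unique(unlist(srcs[i], use.names = FALSE)))
  n_src <- lengths(src_union)
  keep <- n_src >= min_sources
  if (!any(keep)) {
    warning("no gene pair supported by >= ", min_sources, " sources")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  first <- vapply(idx, `[[`, integer(1), 1L)[keep]
  type_lab <- vapply(idx[keep], function(i) {
    paste(unique(types[i]), collapse = "|")
  }, character(1))
  el <- cbind(lo[first], hi[first])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$n_sources <- unname(n_src[keep])
  igraph::E(g)$sources <- vapply(src_union[keep],
                                 paste, character(1), collapse = ";")
  igraph::E(g)$interaction_type <- unname(type_lab)
  g
}

#' Restrict a network to its largest connected component
#'
#' Returns the induced subgraph on the largest connected component,
#' discarding the tiny disconnected fragments typically left after
#' source-support filtering. Ties in component size are broken by the
#' component containing the lexicographically smallest gene symbol, so
#' the result is deterministic.
#'
#' @param net An igraph network from [build_network()].
#' @return The induced subgraph on the winning component.
#' @export
largest_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("cannot take the largest component of an empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    reps <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(reps)[1L]]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Degree histogram of a network
#'
#' Tabulates node counts per degree, the input for a log-log
#' degree-distribution plot used to check scale-free structure.
#'
#' @param net An igraph network.
#' @return A data frame with columns `degree` and `count`; counts sum to
#'   the number of nodes.
#' @export
degree_histogram <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty network")
  tab <- table(igraph::degree(net))
  data.frame(degree = as.integer(names(tab)),
             count = as.integer(tab))
}

#' Write a network or subgraph as Cytoscape SIF
#'
#' One line per edge: `geneA <sep> type <sep> geneB`. The interaction
#' type comes from the `interaction_type` edge attribute when present,
#' falling back to `"pp"`.
#'
#' @param net An igraph network.
#' @param path Output file path.
#' @param sep Field separator (default a single space, the Cytoscape 2.x
#'   dialect).
#' @return The path, invisibly.
#' @export
write_sif <- function(net, path, sep = " ") {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0L) stop("network has no edges; nothing to write")
  el <- igraph::as_edgelist(net)
  type <- igraph::edge_attr(net, "interaction_type")
  if (is.null(type)) type <- rep("pp", nrow(el))
  type[is.na(type) | !nzchar(type)] <- "pp"
  writeLines(paste(el[, 1], type, el[, 2], sep = sep), path)
  invisible(path)
}

#' Read a Cytoscape SIF file back as a network
#'
#' Inverse of [write_sif()]: each line `geneA <sep> type <sep> geneB`
#' becomes an edge with the `interaction_type` attribute set.
#'
#' @param path SIF file path.
#' @param sep Field separator used when writing (default a space).
#' @return An igraph network.
#' @export
read_sif <- function(path, sep = " ") {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) != 3L)) stop("malformed SIF line (need 3 fields)")
  el <- cbind(vapply(fields, `[[`, character(1), 1L),
              vapply(fields, `[[`, character(1), 3L))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$interaction_type <- vapply(fields, `[[`, character(1), 2L)
  g
}
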