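#' Read a weighted gene list
#'
#' Two-column tab-separated file: gene symbol and an optional positive
#' weight. A missing weight column (or field) defaults to 1.0, matching
#' the common case of an unweighted pathway gene list; weights such as
#' per-gene mutation frequencies can be supplied in the second column.
#'
#' @param path Path to the gene-list file.
#' @return A data frame with columns `gene` and `weight`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("gene list is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(fields, `[[`, character(1), 1L)
  weight <- vapply(fields, function(f) {
    if (length(f) >= 2L && nzchar(trimws(f[[2L]]))) as.numeric(f[[2L]]) else 1.0
  }, numeric(1))
  if (anyNA(weight)) stop("non-numeric weight in gene list: ", path)
  data.frame(gene = gene, weight = weight, stringsAsFactors = FALSE)
}

#' Map an input gene list onto the background network
#'
#' Projects user genes onto network nodes. Symbols absent from the
#' network are dropped with a warning and recorded (real gene lists
#' always contain unmapped symbols); duplicated symbols keep their first
#' weight. At least two genes must map for any endpoint pair to exist.
#'
#' @param net Background network (igraph).
#' @param genes Character vector of gene symbols, or a data frame with
#'   columns `gene` and `weight` as returned by [read_gene_list()].
#' @param weights Optional numeric vector of positive weights aligned
#'   with `genes`; defaults to 1 for every gene.
#' @return An object of class `input_gene_set`: a list with `weights`
#'   (named positive numeric vector over mapped nodes) and `dropped`
#'   (character vector of unmapped symbols).
#' @export
map_input_genes <- function(net, genes, weights = NULL) {
  stopifnot(igraph::is_igraph(net))
  if (is.data.frame(genes)) {
    weights <- genes$weight
    genes <- genes$gene
  }
  genes <- as.character(genes)
  if (is.null(weights)) weights <- rep(1.0, length(genes))
  stopifnot(length(weights) == length(genes))
  dup <- duplicated(genes)
  if (any(dup)) {
    warning(sum(dup), " duplicated input symbol(s) ignored")
    genes <- genes[!dup]
    weights <- weights[!dup]
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("all input weights must be strictly positive")
  }
  present <- genes %in% igraph::V(net)$name
  dropped <- genes[!present]
  if (length(dropped) > 0L) {
    warning(length(dropped), " input symbol(s) not in the network were dropped: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  }
  w <- weights[present]
  names(w) <- genes[present]
  if (length(w) < 2L) {
    stop("fewer than 2 input genes mapped onto the network; need at least one endpoint pair")
  }
  structure(list(weights = w, dropped = dropped), class = "input_gene_set")
}

#' @export
print.input_gene_set <- function(x, ...) {
  cat("Input gene set: ", length(x$weights), " mapped node(s), ",
      length(x$dropped), " dropped symbol(s)\n", sep = "")
  invisible(x)
}

# Internal: validate an input_gene_set against a network.
check_inputs <- function(net, inputs) {
  stopifnot(inherits(inputs, "input_gene_set"))
  if (!all(names(inputs$weights) %in% igraph::V(net)$name)) {
    stop("input gene set does not match this network")
  }
  if (length(inputs$weights) < 2L) stop("need at least two input genes")
  if (any(inputs$weights <= 0)) stop("all input weights must be strictly positive")
  invisible(TRUE)
}
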