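#' Monte-Carlo null distribution of nlBC
#'
#' Estimates how surprising each observed centrality value is by
#' recomputing nlBC under `n` random input sets: each replicate samples
#' the same number of nodes as the input list uniformly without
#' replacement from the whole network, maps the original multiset of
#' weights onto them in random order, and recomputes the centrality.
#' For every tracked node the counter `r` records how many replicates
#' reached a value greater than or equal to the observed one.
#'
#' Only nodes with observed nlBC > 0 are tracked: a replicate value of 0
#' always satisfies the comparison when the observed value is 0, so
#' zero-centrality nodes get p-value 1 by construction.
#'
#' All randomness derives from `seed`; the replicate node samples and
#' weight permutations are drawn up front in a fixed order, so results
#' are bit-for-bit reproducible for a given `(seed, n)`.
#'
#' @param net Background network (igraph).
#' @param inputs An `input_gene_set` from [map_input_genes()].
#' @param original The observed `centrality_table` from
#'   [compute_nlbc()] on the same network and inputs.
#' @param n Number of Monte-Carlo replicates (default 20000).
#' @param seed Integer random seed.
#' @param keep_null_samples If `TRUE`, retain the full matrix of
#'   replicate nlBC values for the tracked nodes (for diagnostic
#'   boxplots); off by default to keep memory flat.
#' @return An object of class `null_counters`: list with `r` (named
#'   integer counts over tracked nodes), `n`, `seed`, and
#'   `retained_samples` (a replicates x tracked-nodes matrix, or `NULL`).
#' @export
simulate_null <- function(net, inputs, original, n = 20000L, seed,
                          keep_null_samples = FALSE) {
  check_inputs(net, inputs)
  stopifnot(inherits(original, "centrality_table"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("number of replicates must be >= 1")
  nm <- igraph::V(net)$name
  nv <- length(nm)
  m <- length(inputs$weights)
  if (m > nv) stop("more input genes than network nodes")
  if (!identical(names(original$values), nm)) {
    stop("centrality table does not match this network")
  }
  tracked <- which(original$values > 0)
  w <- as.numeric(inputs$weights)

  draws <- withr::with_seed(as.integer(seed), {
    samples <- matrix(0L, nrow = m, ncol = n)
    wmat <- matrix(0, nrow = m, ncol = n)
    for (j in seq_len(n)) {
      samples[, j] <- sample.int(nv, m)
      wmat[, j] <- w[sample.int(m, m)]
    }
    list(samples = samples, wmat = wmat)
  })

  csr <- as_csr(net)
  res <- .nlbc_null_counts_csr(csr$ptr, csr$adj, csr$n,
                               draws$samples - 1L, draws$wmat,
                               as.numeric(original$values),
                               as.integer(tracked) - 1L,
                               isTRUE(keep_null_samples))
  r <- stats::setNames(as.integer(res$r), nm[tracked])
  samples_out <- NULL
  if (isTRUE(keep_null_samples)) {
    samples_out <- res$samples
    colnames(samples_out) <- nm[tracked]
  }
  structure(list(r = r, n = n, seed = as.integer(seed),
                 retained_samples = samples_out),
            class = "null_counters")
}

#' @export
print.null_counters <- function(x, ...) {
  cat("Monte-Carlo null: ", x$n, " replicates, ", length(x$r),
      " tracked node(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulated p-value
#'
#' The add-one Monte-Carlo estimator \eqn{P_v = (r+1)/(n+1)}, where `r`
#' counts replicates whose statistic met or exceeded the observed value
#' out of `n` replicates. Always strictly positive; the smallest
#' attainable value is `1/(n+1)`.
#'
#' @param r Integer count(s) in `[0, n]`.
#' @param n Number of replicates (>= 1).
#' @return Numeric p-value(s) in `(0, 1]`.
#' @export
p_value <- function(r, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(r < 0) || any(r > n)) stop("r must lie in [0, n]")
  (r + 1) / (n + 1)
}

#' Result table of candidate key molecules
#'
#' Assembles the per-node result rows: gene symbol, degree in the
#' *background* network (not the extracted subgraph), observed nlBC,
#' whether the gene was on the input list, and the simulated p-value.
#' Rows are the tracked nodes with p-value strictly under `alpha`
#' (`alpha >= 1` returns every tracked node), sorted by ascending
#' p-value, ties broken by descending nlBC then gene symbol.
#'
#' @param net Background network (igraph).
#' @param inputs The `input_gene_set`.
#' @param original The observed `centrality_table`.
#' @param counters `null_counters` from [simulate_null()].
#' @param alpha Significance cutoff (default 0.05, strict `<`).
#' @return A data frame with columns `gene`, `degree`, `nlBC`,
#'   `in_input`, `p_value`.
#' @export
build_result_table <- function(net, inputs, original, counters, alpha = 0.05) {
  check_inputs(net, inputs)
  stopifnot(inherits(original, "centrality_table"),
            inherits(counters, "null_counters"))
  genes <- names(counters$r)
  p <- p_value(counters$r, counters$n)
  df <- data.frame(gene = genes,
                   degree = as.integer(igraph::degree(net)[genes]),
                   nlBC = as.numeric(original$values[genes]),
                   in_input = genes %in% names(inputs$weights),
                   p_value = as.numeric(p),
                   stringsAsFactors = FALSE)
  if (alpha < 1) df <- df[df$p_value < alpha, , drop = FALSE]
  df <- df[order(df$p_value, -df$nlBC, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a result table as tab-separated text
#'
#' @param table Result data frame from [build_result_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
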