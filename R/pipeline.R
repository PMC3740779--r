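#' Pipeline run configuration
#'
#' Bundles and validates all parameters of an end-to-end run before any
#' computation starts.
#'
#' @param network_path Path to the interaction table.
#' @param gene_list_path Path to the weighted gene list.
#' @param min_sources Distinct-source edge filter (default 2).
#' @param nsim Monte-Carlo replicates (default 20000).
#' @param seed Integer random seed (required).
#' @param alpha Significance cutoff for the emitted table (default 0.05).
#' @param out_prefix Output path prefix for the result table and run log.
#' @param keep_null_samples Retain per-node replicate values.
#' @param cytoscape If `TRUE`, also write the SIF/.noa bundle at
#'   `out_prefix`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network_path, gene_list_path, out_prefix,
                       min_sources = 2L, nsim = 20000L, seed,
                       alpha = 0.05, keep_null_samples = FALSE,
                       cytoscape = FALSE) {
  if (missing(seed)) stop("a seed is required")
  cfg <- list(network_path = network_path,
              gene_list_path = gene_list_path,
              out_prefix = out_prefix,
              min_sources = as.integer(min_sources),
              nsim = as.integer(nsim),
              seed = as.integer(seed),
              alpha = as.numeric(alpha),
              keep_null_samples = isTRUE(keep_null_samples),
              cytoscape = isTRUE(cytoscape))
  if (!file.exists(cfg$network_path)) stop("network file not readable: ", cfg$network_path)
  if (!file.exists(cfg$gene_list_path)) stop("gene list not readable: ", cfg$gene_list_path)
  if (is.na(cfg$min_sources) || cfg$min_sources < 1L) stop("min_sources must be >= 1")
  if (is.na(cfg$nsim) || cfg$nsim < 1L) stop("nsim must be >= 1")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  if (is.na(cfg$alpha) || cfg$alpha <= 0) stop("alpha must be positive")
  structure(cfg, class = "run_config")
}

#' Run the full hidden-key mining pipeline
#'
#' The three method steps in sequence — map the input genes onto the
#' background network, compute the node-limited betweenness centrality,
#' and validate significance with Monte-Carlo simulated p-values — then
#' write the result table, a run log, and optionally the Cytoscape
#' bundle. Identical inputs and configuration produce byte-identical
#' artifacts.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the result `table`, the `centrality`
#'   table, the `network`, the mapped `inputs`, and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    say(line)
  }

  log("[1/3] mapping input genes onto the network")
  records <- parse_interactions(config$network_path)
  net <- largest_component(build_network(records, config$min_sources))
  log("network: ", igraph::vcount(net), " nodes, ", igraph::ecount(net),
      " edges (min_sources = ", config$min_sources, ")")
  gl <- read_gene_list(config$gene_list_path)
  inputs <- withCallingHandlers(
    map_input_genes(net, gl),
    warning = function(w) {
      log_lines <<- c(log_lines, paste0("warning: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  log("inputs: ", length(inputs$weights), " mapped, ",
      length(inputs$dropped), " dropped",
      if (length(inputs$dropped) > 0)
        paste0(" (", paste(inputs$dropped, collapse = ", "), ")") else "")

  log("[2/3] computing node-limited betweenness centrality")
  centrality <- compute_nlbc(net, inputs)
  log("normalizer w = ", format(centrality$normalizer),
      "; ", sum(centrality$values > 0), " nodes with nonzero nlBC")

  log("[3/3] simulating the null distribution (", config$nsim,
      " replicates, seed ", config$seed, ")")
  counters <- simulate_null(net, inputs, centrality, n = config$nsim,
                            seed = config$seed,
                            keep_null_samples = config$keep_null_samples)
  table <- build_result_table(net, inputs, centrality, counters,
                              alpha = config$alpha)
  log("result: ", nrow(table), " node(s) with p < ", config$alpha)

  table_path <- paste0(config$out_prefix, ".results.tsv")
  write_result_table(table, table_path)
  paths <- table_path
  if (config$cytoscape) {
    sub <- extract_subgraph(net, inputs)
    full <- build_result_table(net, inputs, centrality, counters, alpha = 1)
    paths <- c(paths, export_cytoscape(sub, full, inputs,
                                       config$out_prefix,
                                       centrality = centrality))
  }
  log_path <- paste0(config$out_prefix, ".log")
  writeLines(c(log_lines,
               paste0("nsim = ", config$nsim),
               paste0("seed = ", config$seed),
               paste0("alpha = ", config$alpha)), log_path)
  paths <- c(paths, log_path)

  invisible(list(table = table, centrality = centrality, counters = counters,
                 network = net, inputs = inputs, paths = paths))
}
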