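#' Specification for a synthetic pathway fixture
#'
#' Parameters of the seeded generator that emulates the geometry the
#' miner is designed for: a scale-free background interaction network
#' and a planted signalling motif in which ligand nodes attach only to
#' receptor nodes and receptors bridge to transcription factors drawn
#' from well-connected background nodes. The ligands and transcription
#' factors form the input gene list (the observable entrance and exit of
#' the pathway); the receptors are the "hidden key" ground truth the
#' method should recover. Defaults mirror a receptor-tyrosine-kinase
#' pathway setup: 10 ligands, 4 receptors, 30 transcription factors on a
#' 1000-node background.
#'
#' @param n_background Number of scale-free background nodes.
#' @param attachment Edges added per node during preferential attachment.
#' @param n_ligands,n_receptors,n_tfs Planted motif sizes.
#' @param bridge_extra_degree Extra random background edges given to each
#'   planted receptor, so the hidden keys are tangled into the network
#'   rather than trivially isolated bridges.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `synthetic_pathway_spec`.
#' @export
synthetic_pathway_spec <- function(n_background = 1000L, attachment = 3L,
                                   n_ligands = 10L, n_receptors = 4L,
                                   n_tfs = 30L, bridge_extra_degree = 3L,
                                   seed = 1L) {
  spec <- list(n_background = as.integer(n_background),
               attachment = as.integer(attachment),
               n_ligands = as.integer(n_ligands),
               n_receptors = as.integer(n_receptors),
               n_tfs = as.integer(n_tfs),
               bridge_extra_degree = as.integer(bridge_extra_degree),
               seed = as.integer(seed))
  if (any(vapply(spec, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("all spec fields must be non-negative integers")
  }
  if (spec$n_ligands < 1L || spec$n_receptors < 1L || spec$n_tfs < 1L) {
    stop("motif sizes must be positive")
  }
  if (spec$attachment >= spec$n_background) {
    stop("attachment must be smaller than the background size")
  }
  if (spec$n_background < spec$n_ligands + spec$n_receptors + spec$n_tfs) {
    stop("background too small for the planted motif")
  }
  structure(spec, class = "synthetic_pathway_spec")
}

#' Generate a scale-free background interaction table
#'
#' Draws a preferential-attachment (Barabasi-Albert) graph — connected
#' and heavy-tailed like a source-filtered pathway aggregate — and
#' serializes it as interaction records. Every record carries two
#' synthetic source-database names so the table survives
#' [build_network()] at the default two-source filter unchanged.
#'
#' @param spec A `synthetic_pathway_spec`.
#' @return Interaction records (see [interaction_records()]).
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "synthetic_pathway_spec"))
  g <- withr::with_seed(spec$seed, {
    igraph::sample_pa(spec$n_background, m = spec$attachment,
                      directed = FALSE)
  })
  igraph::V(g)$name <- sprintf("BG%05d", seq_len(spec$n_background))
  el <- igraph::as_edgelist(g)
  interaction_records(el[, 1], el[, 2],
                      rep("pp", nrow(el)),
                      rep(list(c("SynthDB1", "SynthDB2")), nrow(el)))
}

#' Plant a ligand-receptor-TF motif into a background
#'
#' Adds `n_ligands` new ligand nodes, each attached round-robin to
#' exactly one of `n_receptors` new receptor nodes (ligands touch the
#' network only through their receptor), and wires every receptor to a
#' random subset of the transcription factors — chosen as the
#' highest-degree background nodes — plus `bridge_extra_degree` random
#' background nodes. Every ligand-to-TF shortest path therefore crosses
#' a receptor, while the receptors stay far below hub degree.
#'
#' @param records Background interaction records from
#'   [generate_background()].
#' @param spec The same `synthetic_pathway_spec`.
#' @return A list with `records` (background plus planted edges),
#'   `gene_list` (data frame `gene`/`weight`: the ligands and TFs at
#'   uniform weight 1.0) and `planted_keys` (the receptor symbols, the
#'   recovery ground truth).
#' @export
plant_pathway <- function(records, spec) {
  stopifnot(inherits(spec, "synthetic_pathway_spec"), is.data.frame(records))
  bg <- build_network(records, min_sources = 2L)
  if (igraph::vcount(bg) < spec$n_tfs) stop("background smaller than n_tfs")
  deg <- igraph::degree(bg)
  ord <- order(-deg, names(deg))
  tfs <- names(deg)[ord][seq_len(spec$n_tfs)]
  ligands <- sprintf("LIG%03d", seq_len(spec$n_ligands))
  receptors <- sprintf("RCPT%02d", seq_len(spec$n_receptors))

  bg_nodes <- igraph::V(bg)$name
  new_a <- character(0); new_b <- character(0)
  # Ligands attach only to their receptor (round-robin).
  lig_rcpt <- receptors[((seq_len(spec$n_ligands) - 1L) %% spec$n_receptors) + 1L]
  new_a <- c(new_a, ligands)
  new_b <- c(new_b, lig_rcpt)
  withr::with_seed(spec$seed + 1L, {
    for (r in receptors) {
      k <- max(1L, ceiling(spec$n_tfs / 2))
      for (tf in sample(tfs, k)) {
        new_a <- c(new_a, r); new_b <- c(new_b, tf)
      }
      if (spec$bridge_extra_degree > 0L) {
        extra <- sample(setdiff(bg_nodes, tfs), spec$bridge_extra_degree)
        new_a <- c(new_a, rep(r, length(extra)))
        new_b <- c(new_b, extra)
      }
    }
  })
  planted <- interaction_records(new_a, new_b,
                                 rep("pp", length(new_a)),
                                 rep(list(c("SynthDB1", "SynthDB2")),
                                     length(new_a)))
  list(records = rbind(records, planted),
       gene_list = data.frame(gene = c(ligands, tfs),
                              weight = 1.0, stringsAsFactors = FALSE),
       planted_keys = receptors)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the interaction table, the weighted gene list, and a JSON
#' sidecar naming the planted receptors (the answer key for recovery
#' experiments).
#'
#' @param spec A `synthetic_pathway_spec`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_synthetic_fixture <- function(spec, prefix) {
  fx <- plant_pathway(generate_background(spec), spec)
  interactions <- paste0(prefix, ".interactions.tsv")
  src <- vapply(fx$records$sources, paste, character(1), collapse = ";")
  writeLines(paste(fx$records$gene_a, fx$records$gene_b,
                   fx$records$interaction_type, src, sep = "\t"),
             interactions)
  genes <- paste0(prefix, ".genes.tsv")
  writeLines(paste(fx$gene_list$gene, fx$gene_list$weight, sep = "\t"), genes)
  keys <- paste0(prefix, ".planted_keys.json")
  jsonlite::write_json(list(planted_keys = fx$planted_keys, spec = unclass(spec)),
                       keys, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(interactions, genes, keys))
}
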