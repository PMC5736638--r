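#' Prioritize informative signatures and build their redundancy network
#'
#' The full analysis in one call: scores every signature in every dataset
#' by restricted PCA against empirical nulls of random equal-size gene
#' sets ([score_compendium()]), classifies signatures informative when
#' both BH-adjusted p-values pass `alpha` in at least `k_min` datasets
#' ([classify_informative()]), scores cross-dataset eigengene
#' conservation ([conservation_table()]), evaluates compositional and
#' functional redundancy over the selected signature pairs
#' ([redundancy_table()]), and assembles the redundancy network
#' ([build_graph()]). Deterministic given `seed`.
#'
#' @param collection A `signature_collection` (see [read_gmt()]).
#' @param datasets List of `expression_dataset` objects (>= 2 for the
#'   conservation/redundancy/graph stages; with 1 dataset only scoring
#'   and selection run and the later stages are empty).
#' @param alpha Adjusted-p threshold for selection (default 0.05).
#' @param k_min Minimum significant datasets (default 2).
#' @param n_draws Random sets per empirical null (default 1000).
#' @param min_genes Minimum matched genes to score a signature (default 10).
#' @param min_overlap Minimum shared genes for an eigengene pair (default 10).
#' @param min_shared_datasets Minimum shared datasets for a redundancy
#'   pair (default 2).
#' @param conservation_p Threshold on the geometric-mean conservation p
#'   (default 1e-6).
#' @param edge_threshold Functional-redundancy edge threshold, strict
#'   (default 0.7).
#' @param graph_signatures Which signatures become network nodes:
#'   `"informative"` (default) or `"all"` scored signatures.
#' @param seed Integer root seed for all randomness.
#' @return An object of class `infosig` with elements `activity`
#'   (`activity_set`), `calls`, `conservation`, `edges`, `graph`,
#'   `config`.
#' @examples
#' sim <- generate_compendium(synthetic_spec(
#'   n_genes = 400, n_samples = 40, n_planted_modules = 4,
#'   module_size = 20, n_conserved = 2, n_redundant_pairs = 1,
#'   n_background_signatures = 10, seed = 7))
#' fit <- infosig(sim$collection, sim$datasets, n_draws = 99, seed = 7)
#' summary(fit)
#' @export
infosig <- function(collection, datasets, alpha = 0.05, k_min = 2L,
                    n_draws = 1000L, min_genes = 10L, min_overlap = 10L,
                    min_shared_datasets = 2L, conservation_p = 1e-6,
                    edge_threshold = 0.7,
                    graph_signatures = c("informative", "all"),
                    seed = 1L) {
  stopifnot(inherits(collection, "signature_collection"))
  graph_signatures <- match.arg(graph_signatures)
  if (!length(datasets)) stop_("no datasets supplied")
  config <- list(alpha = alpha, k_min = as.integer(k_min),
                 n_draws = as.integer(n_draws),
                 min_genes = as.integer(min_genes),
                 min_overlap = as.integer(min_overlap),
                 min_shared_datasets = as.integer(min_shared_datasets),
                 conservation_p = conservation_p,
                 edge_threshold = edge_threshold,
                 graph_signatures = graph_signatures,
                 seed = as.integer(seed))
  aset <- score_compendium(collection, datasets, n_draws = n_draws,
                           min_genes = min_genes, seed = seed)
  calls <- classify_informative(aset, alpha = alpha, k_min = k_min,
                                signatures = names(collection$signatures))
  multi <- length(datasets) >= 2L
  cons <- if (multi)
    conservation_table(aset, min_overlap = min_overlap,
                       p_threshold = conservation_p)
  else data.frame(signature = character(0), n_pairs = integer(0),
                  score = numeric(0), conserved = logical(0))
  node_names <- if (graph_signatures == "informative")
    calls$signature[calls$informative] else
    calls$signature[calls$scored]
  edges <- NULL
  if (multi && length(node_names) >= 2L)
    edges <- redundancy_table(aset, collection, signatures = node_names,
                              min_shared_datasets = min_shared_datasets,
                              alpha = alpha)
  if (is.null(edges))
    edges <- data.frame(sig_a = character(0), sig_b = character(0),
                        jaccard = numeric(0), ji_pvalue = numeric(0),
                        ji_padj = numeric(0), ji_significant = logical(0),
                        functional_redundancy = numeric(0),
                        n_datasets = integer(0), stringsAsFactors = FALSE)
  graph <- build_graph(edges, calls, cons, collection,
                       signatures = node_names,
                       edge_threshold = edge_threshold)
  structure(list(activity = aset, calls = calls, conservation = cons,
                 edges = edges, graph = graph, config = config,
                 collection = collection),
            class = "infosig")
}

#' @export
print.infosig <- function(x, ...) {
  n_sig <- nrow(x$calls)
  n_inf <- sum(x$calls$informative)
  cat("infosig fit: ", n_sig, " signatures scored in ",
      length(x$activity), " dataset(s)\n", sep = "")
  cat("  informative: ", n_inf, " (alpha = ", x$config$alpha,
      ", k_min = ", x$config$k_min, ")\n", sep = "")
  if (nrow(x$conservation))
    cat("  conserved:   ", sum(x$conservation$conserved, na.rm = TRUE),
        " of ", sum(!is.na(x$conservation$conserved)),
        " classifiable (geometric-mean p < ", x$config$conservation_p,
        ")\n", sep = "")
  cat("  network:     ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (functional redundancy > ",
      x$config$edge_threshold, "), ",
      length(graph_components(x$graph)), " component(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.infosig <- function(object, ...) {
  tab <- activity_table(object$activity)
  cats <- vapply(object$collection$signatures, `[[`, character(1),
                 "category")
  inf_by_cat <- table(cats[object$calls$signature[object$calls$informative]])
  out <- list(
    n_signatures = nrow(object$calls),
    n_datasets = length(object$activity),
    n_informative = sum(object$calls$informative),
    informative_by_category = inf_by_cat,
    n_conserved = sum(object$conservation$conserved, na.rm = TRUE),
    n_edges = igraph::ecount(object$graph),
    component_sizes = lengths(graph_components(object$graph)),
    l1_range = if (nrow(tab)) range(tab$l1) else c(NA, NA),
    config = object$config)
  class(out) <- "summary.infosig"
  out
}

#' @export
print.summary.infosig <- function(x, ...) {
  cat("Informative-signature analysis\n")
  cat("  signatures:", x$n_signatures, " datasets:", x$n_datasets, "\n")
  cat("  informative:", x$n_informative, "\n")
  if (length(x$informative_by_category)) {
    cat("  by category:\n")
    for (nm in names(x$informative_by_category))
      cat("    ", nm, ": ", x$informative_by_category[[nm]], "\n", sep = "")
  }
  cat("  conserved:", x$n_conserved, "\n")
  cat("  network edges:", x$n_edges, " components:",
      paste(x$component_sizes, collapse = "+"), "\n")
  if (!anyNA(x$l1_range))
    cat("  L1 range:", format(x$l1_range[1], digits = 3), "-",
        format(x$l1_range[2], digits = 3), "\n")
  invisible(x)
}

#' Plot an `infosig` fit
#'
#' Renders the redundancy network via [plot.signature_graph()].
#' @param x An `infosig` object.
#' @param ... Passed to [plot.signature_graph()].
#' @export
plot.infosig <- function(x, ...) {
  if (igraph::vcount(x$graph) == 0L) {
    warning("empty graph: nothing to plot")
    return(invisible(x))
  }
  plot(x$graph, ...)
  invisible(x)
}
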