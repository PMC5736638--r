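## The signature redundancy network: nodes are signatures, edges connect
## pairs whose functional redundancy exceeds a threshold. Edge weight
## averages the two redundancy measures; edge class records whether the
## compositional overlap is also significant. Node attributes carry what
## the map renders: category (color), informative (diamond vs circle
## shape), conserved, and gene-set size (node size). Layout is delegated
## to the viewer (e.g. Cytoscape); only attributes are exported.

#' Build the signature redundancy graph
#'
#' @param edges Redundancy table from [redundancy_table()].
#' @param calls Informative calls from [classify_informative()].
#' @param conservation Conservation table from [conservation_table()].
#' @param collection The `signature_collection` (for categories and
#'   gene-set sizes).
#' @param signatures Node set; defaults to `calls$signature`.
#' @param edge_threshold An edge is kept iff `functional_redundancy >
#'   edge_threshold`, strictly (default 0.7).
#' @return An `igraph` object (class also `signature_graph`) with node
#'   attributes `category`, `informative`, `conserved`, `n_genes` and
#'   edge attributes `weight` (mean of Jaccard and functional
#'   redundancy), `functional_redundancy`, `jaccard`, `edge_class`
#'   (`"functional-plus-JI"` when the overlap is significant, else
#'   `"functional-only"`).
#' @export
build_graph <- function(edges, calls, conservation, collection,
                        signatures = NULL, edge_threshold = 0.7) {
  stopifnot(is.data.frame(edges), is.data.frame(calls))
  if (is.null(signatures)) signatures <- calls$signature
  unknown <- setdiff(c(edges$sig_a, edges$sig_b), signatures)
  if (length(unknown))
    stop_("edge references unknown signature(s): ",
          paste(unique(unknown), collapse = ", "))
  keep <- edges$functional_redundancy > edge_threshold
  e <- edges[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(signatures), name = signatures)
  cons <- stats::setNames(conservation$conserved, conservation$signature)
  inf <- stats::setNames(calls$informative, calls$signature)
  sizes <- signature_sizes(collection)
  igraph::V(g)$category <- vapply(signatures, function(nm) {
    s <- collection$signatures[[nm]]
    if (is.null(s)) "" else s$category
  }, character(1))
  igraph::V(g)$informative <- unname(ifelse(is.na(inf[signatures]), FALSE,
                                            inf[signatures]))
  igraph::V(g)$conserved <- unname(ifelse(is.na(cons[signatures]), FALSE,
                                          cons[signatures]))
  igraph::V(g)$n_genes <- unname(ifelse(is.na(sizes[signatures]), 0L,
                                        sizes[signatures]))
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(e$sig_a, e$sig_b),
      weight = (e$jaccard + e$functional_redundancy) / 2,
      functional_redundancy = e$functional_redundancy,
      jaccard = e$jaccard,
      edge_class = ifelse(e$ji_significant, "functional-plus-JI",
                          "functional-only"))
  }
  class(g) <- c("signature_graph", class(g))
  g
}

#' Connected components of the redundancy graph
#'
#' @param graph A `signature_graph`.
#' @return List of character vectors (node names per component), sorted
#'   by size descending.
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(graph)
  members <- split(names(comp$membership), comp$membership)
  unname(members[order(-lengths(members))])
}

#' Export the redundancy graph
#'
#' `graphml` preserves all node/edge attributes; `sif` writes one line
#' per edge with the edge class as the interaction type (plus one
#' node-only line per isolated node); `json` writes a `{nodes, edges}`
#' document with all attributes, suitable for downstream map rendering.
#'
#' @param graph A `signature_graph`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- graph
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(graph)
    lines <- character(0)
    if (nrow(el))
      lines <- paste(el[, 1], igraph::E(graph)$edge_class, el[, 2], sep = "\t")
    iso <- setdiff(igraph::V(graph)$name, as.vector(el))
    writeLines(c(lines, iso), path)
  } else {
    nodes <- data.frame(name = igraph::V(graph)$name,
                        category = igraph::V(graph)$category,
                        informative = igraph::V(graph)$informative,
                        conserved = igraph::V(graph)$conserved,
                        n_genes = igraph::V(graph)$n_genes,
                        stringsAsFactors = FALSE)
    for (a in c("score", "fold_change", "significant"))
      if (a %in% igraph::vertex_attr_names(graph))
        nodes[[a]] <- igraph::vertex_attr(graph, a)
    el <- igraph::as_edgelist(graph)
    edges <- if (nrow(el))
      data.frame(source = el[, 1], target = el[, 2],
                 weight = igraph::E(graph)$weight,
                 functional_redundancy = igraph::E(graph)$functional_redundancy,
                 jaccard = igraph::E(graph)$jaccard,
                 edge_class = igraph::E(graph)$edge_class,
                 stringsAsFactors = FALSE)
    else list()
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Color the map with differential-activity scores
#'
#' Attaches each signature's differential result to its node: nodes with
#' a significant change carry the signed fold change as `score`
#' (positive = upregulation, red semantics; negative = downregulation,
#' green); non-significant nodes carry `NA` (rendered white).
#'
#' @param graph A `signature_graph`.
#' @param diffs Data frame from [differential_table()] (or rows shaped
#'   like [differential_activity()] output plus a `signature` column).
#' @return The graph with node attributes `fold_change`, `significant`
#'   and `score`.
#' @export
score_map <- function(graph, diffs) {
  stopifnot(is.data.frame(diffs))
  unknown <- setdiff(diffs$signature, igraph::V(graph)$name)
  if (length(unknown))
    warning("score_map: skipping result(s) for unknown node(s): ",
            paste(unknown, collapse = ", "))
  diffs <- diffs[diffs$signature %in% igraph::V(graph)$name, , drop = FALSE]
  fc <- stats::setNames(diffs$fold_change, diffs$signature)
  sg <- stats::setNames(diffs$significant, diffs$signature)
  nm <- igraph::V(graph)$name
  igraph::V(graph)$fold_change <- unname(fc[nm])
  igraph::V(graph)$significant <- unname(ifelse(is.na(sg[nm]), FALSE, sg[nm]))
  igraph::V(graph)$score <- ifelse(igraph::V(graph)$significant,
                                   igraph::V(graph)$fold_change, NA_real_)
  graph
}

#' Plot the redundancy graph
#'
#' Base-graphics rendering of the map semantics: node shape square for
#' informative-only signatures, circle for conserved ones; node size
#' proportional to the square root of the gene-set size; edges dark gray
#' when the Jaccard overlap is also significant, light gray otherwise.
#' When differential scores are attached ([score_map()]), significant
#' nodes are shaded red (up) or green (down).
#'
#' @param x A `signature_graph`.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.signature_graph <- function(x, ...) {
  g <- x
  class(g) <- "igraph"
  n <- igraph::vcount(g)
  shape <- ifelse(igraph::V(g)$conserved, "circle", "square")
  size <- 6 + 6 * sqrt(pmax(igraph::V(g)$n_genes, 1)) /
    sqrt(max(igraph::V(g)$n_genes, 1))
  col <- rep("grey90", n)
  if ("score" %in% igraph::vertex_attr_names(g)) {
    sc <- igraph::vertex_attr(g, "score")
    col[!is.na(sc) & sc > 0] <- "indianred2"
    col[!is.na(sc) & sc < 0] <- "palegreen3"
  }
  ecol <- if (igraph::ecount(g))
    ifelse(igraph::E(g)$edge_class == "functional-plus-JI", "grey30", "grey75")
  else NULL
  igraph::plot.igraph(g, vertex.shape = shape, vertex.size = size,
                      vertex.color = col, edge.color = ecol,
                      edge.width = if (igraph::ecount(g))
                        1 + 2 * igraph::E(g)$weight else NULL, ...)
  invisible(x)
}
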