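# Small hand-built inputs for the network construction tests.
graph_fixture <- function() {
  col <- signature_collection(list(
    gene_signature("a", paste0("g", 1:30), "catA"),
    gene_signature("b", paste0("g", 31:50), "catA"),
    gene_signature("c", paste0("g", 51:90), "catB")))
  edges <- data.frame(
    sig_a = c("a", "a", "b"), sig_b = c("b", "c", "c"),
    jaccard = c(0.2, 0.0, 0.1),
    ji_pvalue = c(1e-5, 1, 0.4), ji_padj = c(3e-5, 1, 0.6),
    ji_significant = c(TRUE, FALSE, FALSE),
    functional_redundancy = c(0.8, 0.75, 0.70),
    n_datasets = 3L, stringsAsFactors = FALSE)
  calls <- data.frame(signature = c("a", "b", "c"),
                      n_significant = c(3L, 2L, 2L),
                      significant_datasets = "", informative = TRUE,
                      scored = TRUE, stringsAsFactors = FALSE)
  cons <- data.frame(signature = c("a", "b", "c"), n_pairs = 3L,
                     score = c(8, 2, 7), conserved = c(TRUE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  list(col = col, edges = edges, calls = calls, cons = cons)
}

test_that("graph construction applies the strict edge threshold and classes", {
  fx <- graph_fixture()
  g <- build_graph(fx$edges, fx$calls, fx$cons, fx$col, edge_threshold = 0.7)
  expect_equal(igraph::vcount(g), 3)
  # pair at exactly 0.70 is excluded (strict inequality)
  expect_equal(igraph::ecount(g), 2)
  eattr <- igraph::as_data_frame(g, what = "edges")
  ab <- eattr[eattr$from == "a" & eattr$to == "b", ]
  expect_equal(ab$edge_class, "functional-plus-JI")   # significant JI: dark
  expect_equal(ab$weight, (0.2 + 0.8) / 2)            # mean of both measures
  ac <- eattr[eattr$from == "a" & eattr$to == "c", ]
  expect_equal(ac$edge_class, "functional-only")
  expect_equal(ac$weight, (0.0 + 0.75) / 2)
  # node attributes carry the map semantics
  expect_equal(igraph::V(g)$n_genes, c(30L, 20L, 40L))
  expect_equal(igraph::V(g)$conserved, c(TRUE, FALSE, TRUE))
  expect_equal(igraph::V(g)$category, c("catA", "catA", "catB"))
  # unknown endpoint errors
  bad <- fx$edges; bad$sig_a[1] <- "zzz"
  expect_error(build_graph(bad, fx$calls, fx$cons, fx$col), "unknown")
})

test_that("components are sorted by size and respond to the threshold", {
  fx <- graph_fixture()
  g <- build_graph(fx$edges, fx$calls, fx$cons, fx$col, edge_threshold = 0.7)
  comp <- graph_components(g)
  expect_equal(comp, list(c("a", "b", "c")))
  # raising the threshold never decreases the number of components
  thresholds <- c(0.6, 0.72, 0.77, 0.9)
  n_comp <- vapply(thresholds, function(th)
    length(graph_components(build_graph(fx$edges, fx$calls, fx$cons, fx$col,
                                        edge_threshold = th))), integer(1))
  expect_true(all(diff(n_comp) >= 0))
  # edgeless graph: all singletons
  g0 <- build_graph(fx$edges, fx$calls, fx$cons, fx$col, edge_threshold = 1)
  expect_length(graph_components(g0), 3)
})

test_that("exports preserve node and edge attributes in every format", {
  fx <- graph_fixture()
  g <- build_graph(fx$edges, fx$calls, fx$cons, fx$col)
  # GraphML round-trip
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_true(all(c("category", "informative", "conserved", "n_genes") %in%
                  igraph::vertex_attr_names(g2)))
  expect_true(all(c("weight", "edge_class") %in%
                  igraph::edge_attr_names(g2)))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # SIF: one line per edge, interaction type = class; isolated nodes listed
  fsif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, fsif, "sif")
  lines <- readLines(fsif)
  expect_length(lines, 2)
  expect_true(any(grepl("functional-plus-JI", lines)))
  # JSON schema with scores attached
  diffs <- data.frame(signature = c("a", "b", "c"),
                      fold_change = c(1.5, -0.2, 0.3),
                      significant = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  gs <- score_map(g, diffs)
  fj <- withr::local_tempfile(fileext = ".json")
  export_graph(gs, fj, "json")
  doc <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_setequal(doc$nodes$name, c("a", "b", "c"))
  expect_true(all(c("fold_change", "significant", "score") %in%
                  names(doc$nodes)))
  expect_equal(doc$nodes$score[doc$nodes$name == "a"], 1.5)
  expect_true(is.na(doc$nodes$score[doc$nodes$name == "b"]))
  # empty graph exports are valid in all formats
  g0 <- build_graph(fx$edges[0, ], fx$calls[0, ], fx$cons[0, ], fx$col,
                    signatures = character(0))
  for (fmt in c("graphml", "sif", "json")) {
    fe <- withr::local_tempfile()
    expect_no_error(export_graph(g0, fe, fmt))
  }
  expect_error(export_graph(g, fj, "dot"), "arg")
})

test_that("score_map colors significant nodes and nulls the rest", {
  fx <- graph_fixture()
  g <- build_graph(fx$edges, fx$calls, fx$cons, fx$col)
  diffs <- data.frame(signature = c("a", "c", "nope"),
                      fold_change = c(2.0, -1.0, 5),
                      significant = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  expect_warning(gs <- score_map(g, diffs), "nope")
  sc <- igraph::V(gs)$score
  expect_equal(sc[igraph::V(gs)$name == "a"], 2.0)     # red semantics
  expect_true(is.na(sc[igraph::V(gs)$name == "c"]))    # white semantics
  expect_true(is.na(sc[igraph::V(gs)$name == "b"]))    # no result at all
})
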