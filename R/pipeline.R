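## End-to-end pipeline over files: read GMT + expression TSVs, run
## infosig(), write every artifact with a manifest recording config,
## seed and input digests. Reruns under the same seed and config are
## byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & is.finite(x),
                sprintf("%d", as.integer(x)), sprintf("%.10g", x)))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.10g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write the artifact bundle of an `infosig` fit
#'
#' Writes `activity.tsv` (per signature x dataset scores), `calls.tsv`,
#' `conservation.tsv`, `edges.tsv`, `map.graphml`, `map.json`,
#' `informative.gmt` (the informative subset, when non-empty) and
#' `manifest.json` into `dir`. Output is deterministic: the same fit
#' writes byte-identical files.
#'
#' @param fit An `infosig` object.
#' @param dir Output directory (created if missing).
#' @param inputs Optional named list of input file paths to digest into
#'   the manifest.
#' @return Invisibly, `dir`.
#' @export
write_infosig <- function(fit, dir, inputs = NULL) {
  stopifnot(inherits(fit, "infosig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(activity_table(fit$activity), file.path(dir, "activity.tsv"))
  write_tsv(fit$calls, file.path(dir, "calls.tsv"))
  write_tsv(fit$conservation, file.path(dir, "conservation.tsv"))
  write_tsv(fit$edges, file.path(dir, "edges.tsv"))
  export_graph(fit$graph, file.path(dir, "map.graphml"), "graphml")
  export_graph(fit$graph, file.path(dir, "map.json"), "json")
  inf_names <- fit$calls$signature[fit$calls$informative]
  if (length(inf_names))
    write_gmt(subset_collection(fit$collection, inf_names),
              file.path(dir, "informative.gmt"))
  digests <- if (length(inputs))
    lapply(inputs, function(p) unname(tools::md5sum(p))) else NULL
  manifest <- list(package = "infosig",
                   version = as.character(utils::packageVersion("infosig")),
                   config = fit$config,
                   n_signatures = nrow(fit$calls),
                   n_informative = sum(fit$calls$informative),
                   datasets = names(fit$activity),
                   inputs = digests)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Run the full pipeline over files
#'
#' Reads a GMT signature file and every `*.tsv`/`*.txt` expression matrix
#' in `expr_dir` (one dataset per file, dataset id = file name without
#' extension), runs [infosig()], and writes the artifact bundle with
#' [write_infosig()].
#'
#' @param gmt_path Path to the signature GMT file.
#' @param expr_dir Directory of expression TSV matrices.
#' @param out_dir Output directory.
#' @param ... Passed to [infosig()] (thresholds, `n_draws`, `seed`, ...).
#' @return The `infosig` fit, invisibly.
#' @export
run_pipeline <- function(gmt_path, expr_dir, out_dir, ...) {
  collection <- read_gmt(gmt_path)
  files <- sort(list.files(expr_dir, pattern = "\\.(tsv|txt)$",
                           full.names = TRUE))
  if (!length(files)) stop_("no expression matrices (*.tsv, *.txt) in ",
                            expr_dir)
  datasets <- lapply(files, read_expression)
  fit <- tryCatch(infosig(collection, datasets, ...),
                  error = function(e) stop_("pipeline stage failed: ",
                                            conditionMessage(e)))
  write_infosig(fit, out_dir,
                inputs = c(list(gmt = gmt_path),
                           stats::setNames(as.list(files), basename(files))))
  invisible(fit)
}
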