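#' Create an expression dataset
#'
#' One genes x samples numeric matrix with a dataset identifier (e.g. a
#' cancer-type code). Values are assumed to be on a log-like scale suitable
#' for PCA; this is not enforced. Missing or non-finite values are
#' rejected rather than imputed, since imputation would silently change
#' the PCA-based statistics.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). At least 2 genes and 3
#'   samples.
#' @param dataset_id Dataset identifier string.
#' @return An object of class `expression_dataset` with fields `values`
#'   and `dataset_id`.
#' @export
expression_dataset <- function(values, dataset_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("'values' must carry gene rownames and sample colnames")
  if (nrow(values) < 2L) stop_("need at least 2 genes")
  if (ncol(values) < 3L) stop_("need at least 3 samples")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate gene id(s): ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_("duplicate sample id(s): ",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_("non-finite value at gene '", rownames(values)[bad[1]],
          "', sample '", colnames(values)[bad[2]], "'")
  }
  structure(list(values = values,
                 dataset_id = as.character(dataset_id)[1L]),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset '", x$dataset_id, "': ", nrow(x$values),
      " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated matrix with the first row holding sample ids
#' and the first column holding gene ids. Non-numeric cells (including
#' `NA`) are reported with their gene/sample coordinates.
#'
#' @param path Path to the TSV file.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path,
                            dataset_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop_("expression file has no sample columns: ", path)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop_("duplicate gene row(s): ",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop_("non-numeric or missing value at gene '", gene_ids[bad[1]],
          "', sample '", colnames(m)[bad[2]], "' in ", path)
  }
  rownames(m) <- gene_ids
  expression_dataset(m, dataset_id)
}

#' Write an expression dataset to TSV
#' @param ds An `expression_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Center genes
#'
#' Subtracts the per-gene mean across samples; no variance scaling, since
#' the variance-explained statistics are the object of study. Idempotent.
#'
#' @param ds An `expression_dataset`.
#' @return A gene-centered `expression_dataset`.
#' @export
center_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds$values <- ds$values - rowMeans(ds$values)
  ds
}

#' Define two-group sample labels
#'
#' @param labels Named character vector or factor: `sample id -> group
#'   label`. Exactly two distinct labels, each with at least 2 samples.
#' @param ds Optional `expression_dataset`; if given, every labeled sample
#'   must exist in it.
#' @return An object of class `sample_groups` (named character vector with
#'   attribute `levels`, the two group labels in sort order).
#' @export
sample_groups <- function(labels, ds = NULL) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop_("'labels' must be named by sample id")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop_("need exactly two distinct group labels, got ", length(lev))
  if (any(table(labels) < 2L)) stop_("each group needs at least 2 samples")
  if (!is.null(ds)) {
    miss <- setdiff(names(labels), colnames(ds$values))
    if (length(miss))
      stop_("labeled sample(s) not in dataset: ", paste(miss, collapse = ", "))
  }
  structure(labels, levels = lev, class = "sample_groups")
}
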