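#' Create a gene signature
#'
#' A gene signature is a named, ordered set of gene identifiers with a
#' category label (e.g. the collection it came from, or whether it is
#' data-derived or knowledge-based). Gene identifiers are case-sensitive;
#' duplicates within one signature are collapsed, keeping first occurrence
#' order.
#'
#' @param name Non-empty signature name.
#' @param genes Character vector of gene identifiers (non-empty after
#'   removal of duplicates).
#' @param category Category label; defaults to `""`.
#' @return An object of class `gene_signature` with fields `name`,
#'   `category`, `genes`.
#' @export
gene_signature <- function(name, genes, category = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_("signature name must be a non-empty string")
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_("signature '", name, "' has no genes")
  genes <- genes[!duplicated(genes)]
  structure(list(name = name, category = as.character(category)[1L],
                 genes = genes),
            class = "gene_signature")
}

#' Create a signature collection
#'
#' Bundles gene signatures and exposes the gene universe: every gene
#' appearing in any member signature together with its occurrence count
#' across signatures (the gene-multiplicity pool used by
#' [build_random_signatures()]).
#'
#' @param signatures List of [gene_signature()] objects with unique names.
#' @return An object of class `signature_collection` with fields
#'   `signatures` (named list) and `universe` (named integer vector of
#'   occurrence counts).
#' @export
signature_collection <- function(signatures) {
  if (!is.list(signatures))
    stop_("'signatures' must be a list of gene_signature objects")
  ok <- vapply(signatures, inherits, logical(1), "gene_signature")
  if (length(signatures) && !all(ok))
    stop_("all elements must be gene_signature objects")
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop_("duplicate signature name(s): ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(signatures) <- nms
  pool <- unlist(lapply(signatures, `[[`, "genes"), use.names = FALSE)
  universe <- if (length(pool)) table(pool) else table(character(0))
  universe <- structure(as.integer(universe), names = names(universe))
  structure(list(signatures = signatures, universe = universe),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  sizes <- signature_sizes(x)
  cat("signature_collection:", length(x$signatures), "signatures,",
      length(x$universe), "distinct genes\n")
  if (length(sizes))
    cat("  sizes: min", min(sizes), "/ median", stats::median(sizes),
        "/ max", max(sizes), "\n")
  invisible(x)
}

#' Signature sizes of a collection
#' @param collection A `signature_collection`.
#' @return Named integer vector of gene-set sizes.
#' @export
signature_sizes <- function(collection) {
  vapply(collection$signatures, function(s) length(s$genes), integer(1))
}

#' Read a GMT file
#'
#' GMT is the tab-separated gene-set format: one signature per line,
#' fields `name`, `description`, then gene identifiers. The description
#' field is stored as the signature category unless `category_map`
#' supplies one; duplicate genes within a line are collapsed and the
#' count reported via `message()`.
#'
#' @param path Path to a GMT file.
#' @param category_map Optional named character vector mapping a
#'   signature-name prefix to a category label; the longest matching
#'   prefix wins.
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path, category_map = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sigs <- vector("list", length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop_("malformed GMT line ", i, ": no genes")
    n_dup <- n_dup + sum(duplicated(genes))
    cat_label <- f[2]
    if (!is.null(category_map)) {
      hits <- names(category_map)[startsWith(f[1], names(category_map))]
      if (length(hits))
        cat_label <- category_map[[hits[which.max(nchar(hits))]]]
    }
    sigs[[i]] <- gene_signature(f[1], genes, category = cat_label)
  }
  if (n_dup > 0L)
    message("read_gmt: collapsed ", n_dup, " duplicate gene entr",
            if (n_dup == 1L) "y" else "ies")
  nms <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop_("duplicate signature name in GMT: ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  signature_collection(sigs)
}

#' Write a collection to a GMT file
#'
#' Round-trips exactly with [read_gmt()]: names, categories and gene sets
#' are reproduced. Fields containing a tab character are not representable
#' and raise an error.
#'
#' @param collection A `signature_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "signature_collection"))
  lines <- vapply(collection$signatures, function(s) {
    fields <- c(s$name, s$category, s$genes)
    if (any(grepl("\t", fields, fixed = TRUE)))
      stop_("signature '", s$name,
            "' contains a tab character: not representable in GMT")
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Match a signature against a dataset
#'
#' @param sig A `gene_signature`.
#' @param ds An `expression_dataset`.
#' @return The ordered intersection of the signature's genes with the
#'   dataset's genes; order follows the signature. May be empty.
#' @export
match_signature <- function(sig, ds) {
  stopifnot(inherits(sig, "gene_signature"), inherits(ds, "expression_dataset"))
  sig$genes[sig$genes %in% rownames(ds$values)]
}

#' Subset a collection by signature names
#' @param collection A `signature_collection`.
#' @param names Character vector of member names.
#' @return A `signature_collection` with only the named signatures.
#' @export
subset_collection <- function(collection, names) {
  miss <- setdiff(names, names(collection$signatures))
  if (length(miss)) stop_("unknown signature(s): ", paste(miss, collapse = ", "))
  signature_collection(unname(collection$signatures[names]))
}
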