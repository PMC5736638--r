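## Compositional vs functional redundancy between signature pairs.
##
## Compositional redundancy is gene-set overlap (Jaccard index, with a
## hypergeometric significance test). Functional redundancy is the
## average across datasets of the absolute Pearson correlation between
## the two signatures' metasamples — two disjoint gene sets reading out
## the same underlying program are functionally redundant even at
## Jaccard 0.

#' Jaccard index of two gene sets
#' @param a,b Non-empty character vectors of gene ids.
#' @return `|A n B| / |A u B|` in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  if (!length(a) || !length(b)) stop_("empty gene set")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Hypergeometric significance of a gene-set overlap
#'
#' One-sided upper-tail p-value for observing at least the given overlap
#' between two sets of the given sizes drawn from a universe.
#'
#' @param a,b Character vectors of gene ids, or integers giving the set
#'   sizes (then `overlap` must be supplied).
#' @param universe_size Number of genes in the universe (>= both sizes).
#' @param overlap Overlap size; computed from `a`, `b` when they are
#'   gene vectors.
#' @return p-value in (0, 1].
#' @export
ji_significance <- function(a, b, universe_size, overlap = NULL) {
  if (is.character(a) || is.character(b)) {
    a <- unique(a); b <- unique(b)
    overlap <- length(intersect(a, b))
    a <- length(a); b <- length(b)
  }
  if (is.null(overlap)) stop_("'overlap' required when sizes are given")
  if (a < 1L || b < 1L || a > universe_size || b > universe_size)
    stop_("set sizes must lie in [1, universe_size]")
  if (overlap > min(a, b)) stop_("overlap exceeds the smaller set")
  stats::phyper(overlap - 1, a, universe_size - a, b, lower.tail = FALSE)
}

#' Functional redundancy of two signatures
#'
#' Per shared dataset, the absolute Pearson correlation between the two
#' metasamples (absolute, because the PCA sign is arbitrary per
#' signature and dataset); the value is the arithmetic mean across
#' datasets. Datasets where either signature was unscored are excluded
#' from the mean.
#'
#' @param ms_a,ms_b Named lists `dataset id -> metasample` (named numeric
#'   vectors over the same samples within a dataset).
#' @param min_shared_datasets Minimum shared datasets (default 2); below
#'   it the pair is not evaluable and `NULL` is returned.
#' @return List with `value` (mean absolute correlation),
#'   `per_dataset_r` (named vector) and `n_datasets`, or `NULL`.
#' @export
functional_redundancy <- function(ms_a, ms_b, min_shared_datasets = 2L) {
  shared <- intersect(names(ms_a), names(ms_b))
  if (length(shared) < min_shared_datasets) return(NULL)
  r <- vapply(shared, function(d) {
    x <- ms_a[[d]]; y <- ms_b[[d]]
    if (!identical(names(x), names(y)))
      stop_("metasamples in dataset '", d, "' index different samples")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    abs(stats::cor(x, y))
  }, numeric(1))
  r <- r[!is.na(r)]
  if (length(r) < min_shared_datasets) return(NULL)
  list(value = mean(r), per_dataset_r = r, n_datasets = length(r))
}

#' Pairwise redundancy table
#'
#' Evaluates every unordered pair among the selected signatures: Jaccard
#' index, hypergeometric overlap significance (BH-corrected across all
#' evaluated pairs, significant at `alpha`), and functional redundancy.
#' The hypergeometric universe is the set of all genes appearing in the
#' collection. Pairs sharing fewer than `min_shared_datasets` scored
#' datasets are omitted and reported.
#'
#' @param aset An `activity_set` from [score_compendium()].
#' @param collection The `signature_collection` the activity was scored
#'   on (provides gene memberships and the universe).
#' @param signatures Character vector of signature names to pair up;
#'   defaults to all signatures with metasamples in `aset`.
#' @param min_shared_datasets Minimum shared datasets per pair (default 2).
#' @param alpha BH significance level for the overlap test (default 0.05).
#' @return Data frame, one row per retained pair: `sig_a`, `sig_b`,
#'   `jaccard`, `ji_pvalue`, `ji_padj`, `ji_significant`,
#'   `functional_redundancy`, `n_datasets`.
#' @export
redundancy_table <- function(aset, collection, signatures = NULL,
                             min_shared_datasets = 2L, alpha = 0.05) {
  stopifnot(inherits(aset, "activity_set"),
            inherits(collection, "signature_collection"))
  sets <- unclass(aset)
  if (is.null(signatures))
    signatures <- unique(unlist(lapply(sets, function(s) names(s$metasamples))))
  signatures <- intersect(signatures, names(collection$signatures))
  if (length(signatures) < 2L)
    stop_("need at least 2 signatures to evaluate pairs")
  ms_by_sig <- lapply(signatures, function(nm) {
    out <- lapply(sets, function(s) s$metasamples[[nm]])
    out[!vapply(out, is.null, logical(1))]
  })
  names(ms_by_sig) <- signatures
  universe_size <- length(collection$universe)
  idx <- utils::combn(length(signatures), 2L)
  rows <- vector("list", ncol(idx))
  n_skipped <- 0L
  for (k in seq_len(ncol(idx))) {
    na <- signatures[idx[1, k]]; nb <- signatures[idx[2, k]]
    fr <- functional_redundancy(ms_by_sig[[na]], ms_by_sig[[nb]],
                                min_shared_datasets = min_shared_datasets)
    if (is.null(fr)) { n_skipped <- n_skipped + 1L; next }
    ga <- collection$signatures[[na]]$genes
    gb <- collection$signatures[[nb]]$genes
    rows[[k]] <- data.frame(
      sig_a = na, sig_b = nb,
      jaccard = jaccard_index(ga, gb),
      ji_pvalue = ji_significance(ga, gb, universe_size),
      functional_redundancy = fr$value, n_datasets = fr$n_datasets,
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message("redundancy_table: skipped ", n_skipped,
            " pair(s) with < ", min_shared_datasets, " shared datasets")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(sig_a = character(0), sig_b = character(0),
                      jaccard = numeric(0), ji_pvalue = numeric(0),
                      ji_padj = numeric(0), ji_significant = logical(0),
                      functional_redundancy = numeric(0),
                      n_datasets = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$ji_padj <- bh_adjust(out$ji_pvalue)
  out$ji_significant <- out$ji_padj < alpha
  out[, c("sig_a", "sig_b", "jaccard", "ji_pvalue", "ji_padj",
          "ji_significant", "functional_redundancy", "n_datasets")]
}
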