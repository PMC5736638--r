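## Cross-dataset conservation of signature eigengenes.
##
## A signature whose gene weights (eigengene) are quantitatively
## reproduced from one dataset to another is "conserved". For every
## dataset pair the two eigengenes are correlated over their shared
## genes; the conservation score is the absolute log10 of the geometric
## mean of the correlation p-values.

#' Correlation between two eigengenes
#'
#' Restricts both eigengenes to their shared gene ids and computes the
#' absolute Pearson correlation of the weight vectors. The PCA sign is
#' arbitrary per dataset, so `|r|` is used; the two-sided p-value comes
#' from the t transform `t = |r| sqrt((n-2)/(1-r^2))` with `n - 2`
#' degrees of freedom. p-values are floored at 1e-300 to keep downstream
#' logs finite.
#'
#' @param e1,e2 Named numeric vectors of gene weights (names = gene ids).
#' @param min_overlap Minimum shared genes (default 10); below it the
#'   pair is not comparable and `NULL` is returned.
#' @return List with `r` (absolute correlation), `p` (two-sided p-value)
#'   and `n_shared`, or `NULL` when the overlap is too small.
#' @export
eigengene_correlation <- function(e1, e2, min_overlap = 10L) {
  if (is.null(names(e1)) || is.null(names(e2)))
    stop_("eigengenes must carry gene ids as names")
  shared <- intersect(names(e1), names(e2))
  if (length(shared) < min_overlap) return(NULL)
  x <- e1[shared]; y <- e2[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  r <- abs(stats::cor(x, y))
  n <- length(shared)
  r_ <- min(r, 1 - 1e-15)
  tt <- r_ * sqrt((n - 2) / (1 - r_^2))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1)
  list(r = r, p = p, n_shared = n)
}

#' Conservation score from pairwise p-values
#'
#' `-mean(log10(p))`, i.e. the absolute log10 of the geometric mean of
#' the pairwise Pearson p-values. Higher = more conserved.
#'
#' @param pair_p Non-empty vector of p-values in (0, 1].
#' @return Non-negative score.
#' @export
conservation_score <- function(pair_p) {
  if (!length(pair_p)) stop_("no pairwise p-values")
  if (any(pair_p <= 0 | pair_p > 1)) stop_("p-values must lie in (0, 1]")
  -mean(log10(pair_p))
}

#' Conservation of every signature across the datasets of a compendium
#'
#' For each signature scored in at least two datasets, correlates its
#' eigengenes over all dataset pairs (pairs with too small a gene overlap
#' are skipped) and computes the conservation score. A signature is
#' conserved when the geometric mean of its pairwise p-values is below
#' `p_threshold` (strictly), i.e. its score exceeds
#' `-log10(p_threshold)`.
#'
#' @param aset An `activity_set` from [score_compendium()].
#' @param min_overlap Minimum shared genes per pair (default 10).
#' @param p_threshold Threshold on the geometric mean p (default 1e-6).
#' @return Data frame: `signature`, `n_pairs`, `score`, `conserved`.
#'   Signatures with no valid pair get `n_pairs = 0`, `score = NA`,
#'   `conserved = NA` (unclassifiable).
#' @export
conservation_table <- function(aset, min_overlap = 10L, p_threshold = 1e-6) {
  stopifnot(inherits(aset, "activity_set"))
  sets <- unclass(aset)
  sig_names <- unique(unlist(lapply(sets, function(s) names(s$eigengenes))))
  rows <- lapply(sig_names, function(nm) {
    eigs <- lapply(sets, function(s) s$eigengenes[[nm]])
    eigs <- eigs[!vapply(eigs, is.null, logical(1))]
    pair_p <- numeric(0)
    if (length(eigs) >= 2L) {
      idx <- utils::combn(length(eigs), 2L)
      for (k in seq_len(ncol(idx))) {
        ec <- eigengene_correlation(eigs[[idx[1, k]]], eigs[[idx[2, k]]],
                                    min_overlap = min_overlap)
        if (!is.null(ec)) pair_p <- c(pair_p, ec$p)
      }
    }
    if (!length(pair_p))
      return(data.frame(signature = nm, n_pairs = 0L, score = NA_real_,
                        conserved = NA, stringsAsFactors = FALSE))
    data.frame(signature = nm, n_pairs = length(pair_p),
               score = conservation_score(pair_p),
               conserved = conservation_score(pair_p) > -log10(p_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_uncl <- sum(is.na(out$conserved))
  if (n_uncl > 0L)
    message("conservation_table: ", n_uncl,
            " signature(s) with no valid dataset pair left unclassified")
  out
}

#' Conserved/not-conserved call from a geometric-mean p-value
#'
#' @param geomean_p Geometric mean of the pairwise Pearson p-values.
#' @param p_threshold Strict threshold (default 1e-6).
#' @return `TRUE` iff `geomean_p < p_threshold`.
#' @export
classify_conserved <- function(geomean_p, p_threshold = 1e-6) {
  geomean_p < p_threshold
}
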