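## Restricted PCA and the two overdispersion/coordination statistics.
##
## For one signature in one dataset, PCA is run on the expression matrix
## restricted to the signature's genes, with samples as observations and
## genes as variables. L1 (variance fraction of PC1) measures
## overdispersion; L1/L2 (first-to-second eigenvalue ratio) measures
## coordination. Both are compared against random gene sets of equal size
## drawn from the same dataset.

# Eigenvalues of the sample covariance of t(Z) (samples x genes), Z centered
# genes x samples. Works on the smaller Gram side; values only.
cov_eigenvalues <- function(Z) {
  n <- ncol(Z)
  m <- nrow(Z)
  G <- if (m <= n) tcrossprod(Z) else crossprod(Z)  # m x m or n x n
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values / (n - 1)
  ev <- pmax(ev, 0)
  length(ev) <- min(m, n)
  ev[is.na(ev)] <- 0
  ev
}

#' Restricted PCA of a signature's expression submatrix
#'
#' Computes the PCA of the dataset restricted to the matched genes, with
#' samples as observations and genes as variables. The covariance uses the
#' n-1 denominator, so the variance of the metasample equals the first
#' eigenvalue. The first eigenvector (unit gene loadings) is the
#' signature's eigengene; the centered samples projected on it form the
#' metasample (sample activity profile).
#'
#' The PCA sign is arbitrary; it is fixed so that the Pearson correlation
#' between the metasample and the mean centered expression of the matched
#' genes is non-negative, with exact ties broken by making the
#' largest-magnitude loading positive.
#'
#' @param ds An `expression_dataset` (centered or not; genes are centered
#'   internally).
#' @param matched Character vector of at least 2 gene ids present in `ds`.
#' @return A list with `eigenvalues` (descending, length `min(genes,
#'   samples)`), `eigengene` (named unit vector over matched genes),
#'   `metasample` (named vector over samples).
#' @export
restricted_pca <- function(ds, matched) {
  stopifnot(inherits(ds, "expression_dataset"))
  matched <- as.character(matched)
  if (length(matched) < 2L) stop_("need at least 2 matched genes")
  miss <- setdiff(matched, rownames(ds$values))
  if (length(miss)) stop_("gene(s) not in dataset: ", paste(miss, collapse = ", "))
  Z <- ds$values[matched, , drop = FALSE]
  Z <- Z - rowMeans(Z)
  if (all(Z == 0)) stop_("all-zero submatrix after centering")
  n <- ncol(Z)
  m <- nrow(Z)
  if (m <= n) {
    C <- tcrossprod(Z) / (n - 1)            # m x m gene covariance
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    v1 <- e$vectors[, 1L]
    meta <- drop(crossprod(Z, v1))          # t(Z) %*% v1, length n
  } else {
    G <- crossprod(Z)                       # n x n Gram of samples
    e <- eigen(G, symmetric = TRUE)
    d <- pmax(e$values, 0)
    ev <- d / (n - 1)
    u1 <- e$vectors[, 1L]
    v1 <- drop(Z %*% u1) / sqrt(d[1L])      # back to gene space, unit norm
    meta <- sqrt(d[1L]) * u1
  }
  length(ev) <- min(m, n)
  ev[is.na(ev)] <- 0
  ## deterministic sign
  mean_expr <- colMeans(Z)
  r <- if (stats::sd(meta) > 0 && stats::sd(mean_expr) > 0)
    stats::cor(meta, mean_expr) else 0
  flip <- if (abs(r) > .Machine$double.eps^0.5) r < 0 else
    v1[which.max(abs(v1))] < 0
  if (flip) { v1 <- -v1; meta <- -meta }
  list(eigenvalues = ev,
       eigengene = stats::setNames(v1, matched),
       metasample = stats::setNames(meta, colnames(ds$values)))
}

#' L1 statistic: variance fraction of the first principal component
#' @param eigenvalues Non-negative eigenvalues, not all zero.
#' @return `lambda_1 / sum(lambda)`, in (0, 1].
#' @export
l1_statistic <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop_("negative eigenvalue")
  tot <- sum(eigenvalues)
  if (tot <= 0) stop_("all eigenvalues are zero")
  eigenvalues[1L] / tot
}

#' L1/L2 statistic: first-to-second eigenvalue ratio
#'
#' A rank-1 submatrix (second eigenvalue 0) is maximally coordinated and
#' returns `Inf`.
#'
#' @param eigenvalues Non-negative eigenvalues, at least 2.
#' @return `lambda_1 / lambda_2` (>= 1), or `Inf` when `lambda_2 = 0`.
#' @export
l1l2_statistic <- function(eigenvalues) {
  if (length(eigenvalues) < 2L) stop_("need at least 2 eigenvalues")
  if (any(eigenvalues < 0)) stop_("negative eigenvalue")
  if (eigenvalues[2L] <= 0) return(Inf)
  eigenvalues[1L] / eigenvalues[2L]
}

#' Empirical null distribution for one gene-set size
#'
#' Draws random gene sets of exactly `set_size` genes, uniformly without
#' replacement from the dataset's genes, and records the L1 and L1/L2
#' statistic of each. One null is shared by all signatures of the same
#' matched size in the same dataset.
#'
#' @param ds An `expression_dataset`.
#' @param set_size Number of genes per random set (2..number of genes).
#' @param n_draws Number of random sets.
#' @param seed Integer seed; same seed reproduces the null exactly.
#' @return An object of class `null_distribution` with fields `set_size`,
#'   `dataset_id`, `l1_samples`, `l1l2_samples`, `n_draws`, `seed`.
#' @export
build_null <- function(ds, set_size, n_draws, seed) {
  stopifnot(inherits(ds, "expression_dataset"))
  ng <- nrow(ds$values)
  if (set_size > ng) stop_("set_size (", set_size, ") exceeds gene count (", ng, ")")
  if (set_size < 2L) stop_("set_size must be >= 2")
  if (n_draws < 1L) stop_("n_draws must be >= 1")
  Z <- ds$values - rowMeans(ds$values)
  l1 <- l1l2 <- numeric(n_draws)
  with_seed(seed, {
    for (i in seq_len(n_draws)) {
      idx <- sample.int(ng, set_size)
      ev <- cov_eigenvalues(Z[idx, , drop = FALSE])
      l1[i] <- l1_statistic(ev)
      l1l2[i] <- l1l2_statistic(ev)
    }
  })
  structure(list(set_size = as.integer(set_size), dataset_id = ds$dataset_id,
                 l1_samples = l1, l1l2_samples = l1l2,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "null_distribution")
}

#' Empirical upper-tail p-value
#'
#' Uses the +1 pseudo-count so the p-value is never 0 (required by the
#' downstream BH correction and the conservation log): `p = (1 + #\{null >=
#' observed\}) / (n + 1)`. An infinite observed statistic gets the smallest
#' attainable p, `1/(n+1)`, unless the null itself contains infinities.
#'
#' @param observed Observed statistic.
#' @param null_samples Non-empty numeric vector of null statistics.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_samples) {
  if (!length(null_samples)) stop_("empty null sample")
  (1 + sum(null_samples >= observed)) / (length(null_samples) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort, take running minima of
#' `p_(j) * m / j` from the top, cap at 1, return in input order.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop_("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Score a signature collection in one dataset
#'
#' For every signature with at least `min_genes` matched genes, runs the
#' restricted PCA, computes L1 and L1/L2, and derives empirical p-values
#' from a null of random equal-size gene sets (one null per matched size,
#' shared across signatures). BH adjustment is applied across all scored
#' signatures, separately for the L1 and the L1/L2 family.
#'
#' @param collection A `signature_collection`.
#' @param ds An `expression_dataset`.
#' @param n_draws Random sets per null distribution (default 1000; the
#'   smallest attainable p is `1/(n_draws+1)`, which bounds how small an
#'   adjusted p can get — see the methods vignette).
#' @param min_genes Minimum matched genes for a signature to be scored
#'   (default 10); signatures below it are skipped and reported.
#' @param seed Root seed; per-size null streams are derived from it.
#' @return An object of class `activity_scores`: `table` (one row per
#'   scored signature: `signature`, `dataset`, `n_matched`, `l1`, `l1l2`,
#'   `p_l1`, `p_l1l2`, `padj_l1`, `padj_l1l2`), `eigengenes` and
#'   `metasamples` (named lists of named vectors), `skipped` (character),
#'   `dataset_id`, `n_draws`, `seed`.
#' @export
score_collection <- function(collection, ds, n_draws = 1000L, min_genes = 10L,
                             seed = 1L) {
  stopifnot(inherits(collection, "signature_collection"),
            inherits(ds, "expression_dataset"))
  cds <- center_genes(ds)
  matched <- lapply(collection$signatures, match_signature, ds = cds)
  sizes <- lengths(matched)
  keep <- sizes >= max(2L, min_genes)
  skipped <- names(collection$signatures)[!keep]
  if (length(skipped))
    message("score_collection[", ds$dataset_id, "]: skipped ", length(skipped),
            " signature(s) with < ", min_genes, " matched genes")
  sig_names <- names(collection$signatures)[keep]
  if (!length(sig_names))
    return(structure(list(table = empty_activity_table(),
                          eigengenes = list(), metasamples = list(),
                          skipped = skipped, dataset_id = ds$dataset_id,
                          n_draws = as.integer(n_draws),
                          seed = as.integer(seed)),
                     class = "activity_scores"))
  nulls <- list()
  for (s in sort(unique(sizes[keep]))) {
    nulls[[as.character(s)]] <- build_null(
      cds, s, n_draws = n_draws,
      seed = derive_seed(seed, "null", ds$dataset_id, s))
  }
  eig <- meta <- stats::setNames(vector("list", length(sig_names)), sig_names)
  l1 <- l1l2 <- p1 <- p12 <- numeric(length(sig_names))
  for (i in seq_along(sig_names)) {
    nm <- sig_names[i]
    pca <- restricted_pca(cds, matched[[nm]])
    l1[i] <- l1_statistic(pca$eigenvalues)
    l1l2[i] <- l1l2_statistic(pca$eigenvalues)
    nd <- nulls[[as.character(length(matched[[nm]]))]]
    p1[i] <- empirical_pvalue(l1[i], nd$l1_samples)
    p12[i] <- empirical_pvalue(l1l2[i], nd$l1l2_samples)
    eig[[nm]] <- pca$eigengene
    meta[[nm]] <- pca$metasample
  }
  tab <- data.frame(signature = sig_names, dataset = ds$dataset_id,
                    n_matched = unname(sizes[keep][sig_names]),
                    l1 = l1, l1l2 = l1l2, p_l1 = p1, p_l1l2 = p12,
                    padj_l1 = bh_adjust(p1), padj_l1l2 = bh_adjust(p12),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, eigengenes = eig, metasamples = meta,
                 skipped = skipped, dataset_id = ds$dataset_id,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "activity_scores")
}

empty_activity_table <- function() {
  data.frame(signature = character(0), dataset = character(0),
             n_matched = integer(0), l1 = numeric(0), l1l2 = numeric(0),
             p_l1 = numeric(0), p_l1l2 = numeric(0), padj_l1 = numeric(0),
             padj_l1l2 = numeric(0), stringsAsFactors = FALSE)
}

#' Score a collection across a compendium of datasets
#'
#' Runs [score_collection()] on each dataset; each dataset gets its own
#' derived seed stream and its own BH families.
#'
#' @inheritParams score_collection
#' @param datasets List of `expression_dataset` objects with distinct ids.
#' @return An object of class `activity_set`: a named list of
#'   `activity_scores`, one per dataset.
#' @export
score_compendium <- function(collection, datasets, n_draws = 1000L,
                             min_genes = 10L, seed = 1L) {
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop_("duplicate dataset ids")
  out <- lapply(datasets, function(ds)
    score_collection(collection, ds, n_draws = n_draws, min_genes = min_genes,
                     seed = derive_seed(seed, "dataset", ds$dataset_id)))
  names(out) <- ids
  structure(out, class = "activity_set")
}

#' Combined activity table of an `activity_set`
#' @param aset An `activity_set` from [score_compendium()].
#' @return One data frame, rows of all per-dataset tables stacked.
#' @export
activity_table <- function(aset) {
  stopifnot(inherits(aset, "activity_set"))
  do.call(rbind, c(lapply(unclass(aset), `[[`, "table"),
                   list(make.row.names = FALSE)))
}
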