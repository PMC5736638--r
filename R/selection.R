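## Informative-signature selection: combine per-dataset activity scores
## into informative calls, and estimate the procedure's FDR with a null
## model of random signatures.

#' Classify signatures as informative
#'
#' A signature is informative when both BH-adjusted p-values (L1 and
#' L1/L2) fall below `alpha` in at least `k_min` datasets — i.e. it is
#' simultaneously overdispersed and coordinated in several datasets.
#' Datasets where a signature was unscored (too few matched genes) count
#' as non-significant, not as missing.
#'
#' @param activity An `activity_set` from [score_compendium()], or the
#'   combined data frame from [activity_table()].
#' @param alpha Significance threshold on the adjusted p-values (default
#'   0.05).
#' @param k_min Minimum number of datasets in which both adjusted
#'   p-values must pass (default 2).
#' @param signatures Optional character vector of signature names to
#'   report on (so signatures scored nowhere still get a call with
#'   `n_significant = 0` and `scored = FALSE`); defaults to the
#'   signatures present in `activity`.
#' @return Data frame, one row per signature: `signature`,
#'   `n_significant`, `significant_datasets` (comma-separated ids),
#'   `informative`, `scored`.
#' @export
classify_informative <- function(activity, alpha = 0.05, k_min = 2L,
                                 signatures = NULL) {
  tab <- if (inherits(activity, "activity_set")) activity_table(activity)
         else activity
  stopifnot(is.data.frame(tab))
  if (!(alpha > 0 && alpha < 1)) stop_("alpha must lie in (0, 1)")
  if (k_min < 1L) stop_("k_min must be >= 1")
  if (is.null(signatures)) signatures <- unique(tab$signature)
  hit <- tab$padj_l1 < alpha & tab$padj_l1l2 < alpha
  hits_by_sig <- split(tab$dataset[hit], factor(tab$signature[hit],
                                                levels = signatures))
  n_sig <- lengths(hits_by_sig)
  data.frame(
    signature = signatures,
    n_significant = unname(n_sig[signatures]),
    significant_datasets = vapply(hits_by_sig[signatures], paste,
                                  character(1), collapse = ","),
    informative = unname(n_sig[signatures]) >= k_min,
    scored = signatures %in% tab$signature,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build random signatures from a reference collection
#'
#' Emulates the composition of a reference collection: sizes are drawn
#' from its empirical size distribution (stratified over 100 size
#' percentile bins, bins picked proportionally to occupancy, sizes
#' uniform within a bin) and genes are drawn from the pool of all gene
#' occurrences with multiplicity preserved — a gene appearing in 100
#' signatures is 100 times as likely to be picked as one appearing once —
#' without replacement within one signature.
#'
#' @param collection Reference `signature_collection` (non-empty).
#' @param n Number of random signatures to build.
#' @param seed Integer seed.
#' @return A `signature_collection` of `n` signatures named
#'   `RANDOM_0001` ... with category `"random"`.
#' @export
build_random_signatures <- function(collection, n, seed) {
  stopifnot(inherits(collection, "signature_collection"))
  if (length(collection$signatures) == 0L) stop_("empty reference collection")
  if (n < 1L) stop_("n must be >= 1")
  sizes <- sort(signature_sizes(collection))
  n_bins <- min(100L, length(sizes))
  bin_of <- ceiling(seq_along(sizes) / length(sizes) * n_bins)
  by_bin <- split(sizes, bin_of)
  universe <- collection$universe
  gene_names <- names(universe)
  n_distinct <- length(gene_names)
  if (min(sizes) > n_distinct)
    stop_("every reference size exceeds the distinct-gene count")
  n_resampled <- 0L
  sigs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        b <- by_bin[[sample.int(length(by_bin), 1L)]]
        s <- b[[sample.int(length(b), 1L)]]
        if (s <= n_distinct) break
        n_resampled <<- n_resampled + 1L
      }
      genes <- sample(gene_names, s, prob = universe)
      gene_signature(sprintf("RANDOM_%04d", i), genes, category = "random")
    })
  })
  if (n_resampled > 0L)
    message("build_random_signatures: resampled ", n_resampled,
            " size(s) exceeding the distinct-gene count")
  signature_collection(sigs)
}

#' Estimate the selection FDR with a null model of random signatures
#'
#' Builds `n_random` random signatures from the reference collection,
#' scores them in every dataset and classifies them with the standard
#' rule; the fraction called informative estimates the false-discovery
#' rate of the whole selection procedure.
#'
#' @param collection Reference `signature_collection` (provides the size
#'   distribution and the gene-multiplicity pool).
#' @param datasets List of `expression_dataset` objects.
#' @param n_random Number of random signatures (default 1000).
#' @param alpha,k_min Selection thresholds, as in [classify_informative()].
#' @param n_draws Random sets per empirical null (default 100: the null
#'   model spans many distinct set sizes and only the tail behaviour under
#'   the null matters here, not p-value resolution).
#' @param min_genes Minimum matched genes, as in [score_collection()].
#' @param seed Integer root seed.
#' @return An object of class `null_model_report`: `n_random`,
#'   `n_called_informative`, `fdr_estimate`, `seed`, and the per-signature
#'   `calls` data frame.
#' @export
estimate_fdr <- function(collection, datasets, n_random = 1000L,
                         alpha = 0.05, k_min = 2L, n_draws = 100L,
                         min_genes = 10L, seed = 1L) {
  if (n_random < 1L) stop_("n_random must be >= 1")
  rand <- build_random_signatures(collection, n_random,
                                  seed = derive_seed(seed, "random-signatures"))
  aset <- score_compendium(rand, datasets, n_draws = n_draws,
                           min_genes = min_genes,
                           seed = derive_seed(seed, "null-model-scoring"))
  calls <- classify_informative(aset, alpha = alpha, k_min = k_min,
                                signatures = names(rand$signatures))
  n_inf <- sum(calls$informative)
  structure(list(n_random = as.integer(n_random),
                 n_called_informative = n_inf,
                 fdr_estimate = n_inf / n_random,
                 seed = as.integer(seed), calls = calls),
            class = "null_model_report")
}

#' @export
print.null_model_report <- function(x, ...) {
  cat("null_model_report:", x$n_called_informative, "of", x$n_random,
      "random signatures called informative (FDR estimate ",
      format(100 * x$fdr_estimate), "%)\n")
  invisible(x)
}
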