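# Small in-code fixtures shared across test files.

# expression_dataset from a bare matrix, auto gene/sample names
make_ds <- function(m, id = "DS") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_dataset(m, id)
}

# fixed 3 genes x 6 samples matrix used by the PCA oracle tests
fixture_3x6 <- function() {
  m <- matrix(c(1.2, -0.7,  0.3,  2.1, -1.5,  0.6,
                0.4,  1.9, -2.2,  0.8,  0.1, -1.0,
               -0.9,  0.5,  1.4, -0.3,  2.0, -2.7),
              nrow = 3, byrow = TRUE)
  make_ds(m, "FIX")
}

# brute-force PCA oracle: dense covariance eigendecomposition with
# samples as observations, genes as variables
pca_oracle <- function(ds, genes = rownames(ds$values)) {
  Z <- ds$values[genes, , drop = FALSE]
  Z <- Z - rowMeans(Z)
  C <- stats::cov(t(Z))                 # genes x genes, n-1 denominator
  eigen(C, symmetric = TRUE)
}

# small random collection over a gene pool
random_collection <- function(n_sigs, size, pool, prefix = "SIG") {
  signature_collection(lapply(seq_len(n_sigs), function(i)
    gene_signature(sprintf("%s_%03d", prefix, i), sample(pool, size))))
}

# activity-style table row for selection tests
act_row <- function(sig, ds, p1, p2) {
  data.frame(signature = sig, dataset = ds, n_matched = 20L,
             l1 = 0.2, l1l2 = 1.5, p_l1 = p1, p_l1l2 = p2,
             padj_l1 = p1, padj_l1l2 = p2, stringsAsFactors = FALSE)
}
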