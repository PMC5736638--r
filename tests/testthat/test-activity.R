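test_that("restricted PCA matches a dense covariance eigendecomposition", {
  ds <- fixture_3x6()
  oracle <- pca_oracle(ds)
  pca <- restricted_pca(ds, rownames(ds$values))
  expect_equal(pca$eigenvalues, pmax(oracle$values, 0), tolerance = 1e-9)
  # eigenvector agreement up to sign
  expect_equal(abs(sum(pca$eigengene * oracle$vectors[, 1])), 1,
               tolerance = 1e-9)
  expect_equal(sqrt(sum(pca$eigengene^2)), 1, tolerance = 1e-9)
  # metasample variance equals the first eigenvalue (n-1 denominator)
  expect_equal(var(pca$metasample), pca$eigenvalues[1], tolerance = 1e-9)
  # trace identity: sum of eigenvalues = total variance of centered matrix
  Z <- ds$values - rowMeans(ds$values)
  expect_equal(sum(pca$eigenvalues), sum(Z^2) / (ncol(Z) - 1),
               tolerance = 1e-9)
})

test_that("both PCA code paths (genes <= samples and genes > samples) agree", {
  set.seed(42)
  m <- matrix(rnorm(15 * 8), nrow = 15,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
  ds <- expression_dataset(m, "WIDE")      # genes > samples: Gram path
  oracle <- pca_oracle(ds)
  pca <- restricted_pca(ds, rownames(m))
  k <- ncol(m)
  expect_equal(pca$eigenvalues[1:k], pmax(oracle$values[1:k], 0),
               tolerance = 1e-8)
  expect_equal(abs(sum(pca$eigengene * oracle$vectors[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(var(pca$metasample), pca$eigenvalues[1], tolerance = 1e-8)
})

test_that("a rank-1 gene pair yields eigenvalue gap and proportional loadings", {
  g1 <- c(1, 3, -2, 0.5, -1.5, 2)
  ds <- make_ds(rbind(g1 = g1, g2 = 2 * g1))
  pca <- restricted_pca(ds, c("g1", "g2"))
  expect_equal(pca$eigenvalues[2], 0, tolerance = 1e-12)
  expect_equal(abs(pca$eigengene), c(g1 = 1, g2 = 2) / sqrt(5),
               tolerance = 1e-9)
  expect_equal(l1l2_statistic(pca$eigenvalues), Inf)
  expect_error(restricted_pca(make_ds(rbind(rep(1, 4), rep(2, 4))),
                              c("g1", "g2")), "all-zero")
})

test_that("the deterministic sign rule orients the metasample", {
  set.seed(7)
  ds <- make_ds(matrix(rnorm(5 * 30), nrow = 5))
  pca <- restricted_pca(ds, rownames(ds$values))
  Z <- ds$values - rowMeans(ds$values)
  expect_gte(cor(pca$metasample, colMeans(Z)), 0)
  # negating the data: the rule re-orients against the negated mean
  # expression, so the gene loadings are reproduced and the metasample flips
  ds2 <- ds; ds2$values <- -ds2$values
  pca2 <- restricted_pca(ds2, rownames(ds$values))
  expect_equal(pca2$eigengene, pca$eigengene, tolerance = 1e-9)
  expect_equal(pca2$metasample, -pca$metasample, tolerance = 1e-9)
})

test_that("L1 and L1/L2 statistics follow their definitions", {
  expect_equal(l1_statistic(c(4, 0, 0)), 1.0)
  expect_equal(l1_statistic(c(2, 1, 1)), 0.5)
  expect_equal(l1l2_statistic(c(2, 1)), 2.0)
  expect_equal(l1l2_statistic(c(3, 3)), 1.0)
  expect_error(l1_statistic(c(0, 0)), "zero")
  expect_error(l1l2_statistic(5), "at least 2")
  ds <- fixture_3x6()
  ev <- pmax(pca_oracle(ds)$values, 0)
  pca <- restricted_pca(ds, rownames(ds$values))
  expect_equal(l1_statistic(pca$eigenvalues), ev[1] / sum(ev),
               tolerance = 1e-9)
})

test_that("L1 is invariant under sample permutation and gene reordering", {
  set.seed(11)
  ds <- make_ds(matrix(rnorm(8 * 12), nrow = 8))
  l1_of <- function(d, genes) l1_statistic(restricted_pca(d, genes)$eigenvalues)
  base <- l1_of(ds, rownames(ds$values))
  perm <- ds; perm$values <- perm$values[, sample(ncol(perm$values))]
  expect_equal(l1_of(perm, rownames(ds$values)), base, tolerance = 1e-12)
  expect_equal(l1_of(ds, rev(rownames(ds$values))), base, tolerance = 1e-12)
})

test_that("empirical p-values use the +1 pseudo-count upper tail", {
  expect_equal(empirical_pvalue(100, 1:99), 1 / 100)
  expect_equal(empirical_pvalue(0, 1:99), 1.0)
  null <- seq(-50, 50)                      # 101 distinct values, median 0
  expect_equal(empirical_pvalue(0, null), (1 + 51) / 102)
  expect_equal(empirical_pvalue(Inf, 1:99), 1 / 100)
  # monotone non-increasing in the observed statistic
  obs <- sort(rnorm(20))
  p <- vapply(obs, empirical_pvalue, numeric(1), null_samples = rnorm(50))
  expect_true(all(diff(p) <= 0))
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # adjusted >= raw, ordering preserved
  set.seed(3)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("null distributions are reproducible and self-consistent", {
  ds <- make_ds(matrix(rnorm(300 * 40), nrow = 300), "NOISE")
  n1 <- build_null(ds, 25, n_draws = 60, seed = 5)
  n2 <- build_null(ds, 25, n_draws = 60, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$l1_samples > 0 & n1$l1_samples <= 1))
  expect_true(all(n1$l1l2_samples >= 1))
  # Monte-Carlo self-consistency: two independent seeds agree on mean L1
  n3 <- build_null(ds, 25, n_draws = 60, seed = 99)
  se <- sqrt(var(n1$l1_samples) / 60 + var(n3$l1_samples) / 60)
  expect_lt(abs(mean(n1$l1_samples) - mean(n3$l1_samples)), 3 * se)
  # set_size equal to the gene count: every draw is the full set
  nfull <- build_null(make_ds(matrix(rnorm(5 * 20), nrow = 5)), 5,
                      n_draws = 10, seed = 1)
  expect_equal(length(unique(round(nfull$l1_samples, 12))), 1L)
  expect_error(build_null(ds, 301, 10, 1), "exceeds")
})

test_that("score_collection skips small signatures and fills the table", {
  set.seed(8)
  ds <- make_ds(matrix(rnorm(100 * 30), nrow = 100), "D1")
  col <- signature_collection(list(
    gene_signature("BIG", rownames(ds$values)[1:20]),
    gene_signature("SMALL", rownames(ds$values)[1:3]),
    gene_signature("UNMATCHED", paste0("zz", 1:15))))
  expect_message(
    scores <- score_collection(col, ds, n_draws = 49, min_genes = 10,
                               seed = 2),
    "skipped 2")
  expect_equal(scores$table$signature, "BIG")
  expect_setequal(scores$skipped, c("SMALL", "UNMATCHED"))
  expect_equal(names(scores$eigengenes$BIG), rownames(ds$values)[1:20])
  expect_length(scores$metasamples$BIG, 30)
  expect_true(all(scores$table$p_l1 > 0 & scores$table$p_l1 <= 1))
  # deterministic under the same seed
  s2 <- suppressMessages(score_collection(col, ds, n_draws = 49,
                                          min_genes = 10, seed = 2))
  expect_equal(s2$table, scores$table)
})

test_that("on pure noise the p-values are not anti-conservative", {
  set.seed(21)
  ds <- make_ds(matrix(rnorm(300 * 40), nrow = 300), "NOISE")
  col <- random_collection(40, 15, rownames(ds$values))
  scores <- score_collection(col, ds, n_draws = 199, seed = 6)
  p <- scores$table$p_l1
  # empirical cdf at a grid never exceeds uniform beyond binomial noise
  for (q in c(0.1, 0.25, 0.5, 0.75)) {
    expect_lte(mean(p <= q), q + 3 * sqrt(q * (1 - q) / length(p)))
  }
})
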