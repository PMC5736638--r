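test_that("generated compendia satisfy the container invariants", {
  spec <- synthetic_spec(n_datasets = 3, n_genes = 400, n_samples = 30,
                         n_planted_modules = 4, module_size = 20,
                         n_conserved = 2, n_redundant_pairs = 2,
                         n_background_signatures = 15, seed = 3)
  sim <- generate_compendium(spec)
  expect_length(sim$datasets, 3)
  for (ds in sim$datasets) {
    expect_s3_class(ds, "expression_dataset")
    expect_equal(dim(ds$values), c(400L, 30L))
  }
  expect_length(sim$collection$signatures, 4 + 2 * 2 + 15)
  # planted gene sets are pairwise disjoint
  planted <- sim$truth$signature[sim$truth$planted]
  genes <- lapply(sim$collection$signatures[planted], `[[`, "genes")
  expect_equal(length(unique(unlist(genes))), length(unlist(genes)))
  # truth table is consistent
  expect_equal(sum(sim$truth$conserved_planted), 2)
  expect_equal(sim$truth$redundant_partner[
    sim$truth$signature == "REDUNDANT_01A"], "REDUNDANT_01B")
  both <- sim$truth[sim$truth$signature %in%
                    c("REDUNDANT_02A", "REDUNDANT_02B"), ]
  expect_equal(both$latent_factor_id[1], both$latent_factor_id[2])
  # determinism
  sim2 <- generate_compendium(spec)
  expect_identical(sim$datasets[[2]]$values, sim2$datasets[[2]]$values)
  expect_identical(sim$collection$signatures, sim2$collection$signatures)
  # infeasible specs are rejected up front
  expect_error(synthetic_spec(n_genes = 50, n_planted_modules = 10,
                              module_size = 20), "demand")
})

test_that("a planted module's top eigenvalue follows the factor-model closed form", {
  # lambda_1 ~ m * loading_scale^2 + noise_sd^2 for m equal-magnitude loadings
  spec <- synthetic_spec(n_datasets = 1, n_genes = 300, n_samples = 200,
                         n_planted_modules = 1, module_size = 30,
                         loading_scale = 1.5, noise_sd = 1, n_conserved = 0,
                         n_redundant_pairs = 0, n_background_signatures = 0,
                         seed = 12)
  sim <- generate_compendium(spec)
  genes <- sim$collection$signatures$MODULE_01$genes
  ev <- restricted_pca(sim$datasets[[1]], genes)$eigenvalues
  expected <- 30 * 1.5^2 + 1
  # lambda_1 estimate fluctuates ~ lambda_1 * sqrt(2/n)
  expect_lt(abs(ev[1] - expected), 4 * expected * sqrt(2 / 200))
  # remaining eigenvalues stay near the noise level
  expect_lt(ev[2], 4)
})

test_that("loading_scale 0 degenerates to pure noise", {
  spec <- synthetic_spec(n_datasets = 1, n_genes = 200, n_samples = 50,
                         n_planted_modules = 2, module_size = 20,
                         loading_scale = 0, n_conserved = 0,
                         n_redundant_pairs = 0, n_background_signatures = 0,
                         seed = 8)
  sim <- generate_compendium(spec)
  genes <- sim$collection$signatures$MODULE_01$genes
  ev <- restricted_pca(sim$datasets[[1]], genes)$eigenvalues
  # dominant eigenvalue stays at the Marchenko-Pastur edge for noise:
  # (1 + sqrt(p/n))^2 ~ 2.6 here; nothing module-like
  expect_lt(l1_statistic(ev), 0.2)
})

test_that("the null compendium is structureless and reproducible", {
  sets <- generate_null_compendium(2, 500, 80, seed = 21)
  expect_length(sets, 2)
  X <- sets[[1]]$values
  # per-gene means vanish within 4 sigma / sqrt(n)
  expect_lt(max(abs(rowMeans(X))), 4 / sqrt(80))
  # cross-correlation between disjoint gene blocks sits at the null level
  r <- cor(t(X[1:20, ]), t(X[21:40, ]))
  expected_mean_abs <- sqrt(2 / (pi * (80 - 1)))
  sd_abs <- sqrt((1 - 2 / pi) / (80 - 1))
  expect_lt(abs(mean(abs(r)) - expected_mean_abs), 3 * sd_abs / sqrt(20))
  expect_identical(generate_null_compendium(2, 500, 80, seed = 21)[[1]]$values,
                   X)
})

test_that("two-condition data carry a balanced split and shift truth", {
  spec <- synthetic_spec(n_genes = 300, n_samples = 40,
                         n_planted_modules = 3, module_size = 20,
                         n_conserved = 0, n_redundant_pairs = 1,
                         n_background_signatures = 0, group_shift = 2,
                         seed = 15)
  tc <- generate_two_condition(spec)
  expect_equal(as.integer(table(unclass(tc$groups))), c(20L, 20L))
  expect_equal(tc$truth$shifted,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  tc2 <- generate_two_condition(spec)
  expect_identical(tc$dataset$values, tc2$dataset$values)
  # shift 0 marks nothing as shifted
  tc0 <- generate_two_condition(spec, group_shift = 0)
  expect_false(any(tc0$truth$shifted))
})
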