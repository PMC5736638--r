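## Synthetic multi-dataset compendia with known ground truth.
##
## A Gaussian latent-factor model: each planted module is a block of
## genes tied to one latent factor whose per-sample activity is standard
## normal; gene values are loading * activity + Gaussian noise. This is
## the minimal structure with a distinguishable principal axis, which is
## exactly what the informative-signature statistics detect. Conserved
## modules reuse one loading vector across datasets; redundant pairs are
## two disjoint gene sets attached to the same factor; background
## signatures are random sets of unassigned (pure-noise) genes.

#' Specification of a synthetic compendium
#'
#' @param n_datasets Number of datasets (default 4).
#' @param n_genes Genes per dataset (default 5000).
#' @param n_samples Samples per dataset (default 100).
#' @param n_planted_modules Planted modules (default 20).
#' @param module_size Genes per planted module / per redundant set / per
#'   background signature (default 50).
#' @param loading_scale Magnitude of each planted gene loading (default
#'   1); 0 degenerates to pure noise.
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param n_conserved Planted modules (the first ones) that reuse one
#'   loading vector across all datasets (default 10); the rest redraw
#'   loadings per dataset.
#' @param n_redundant_pairs Disjoint gene-set pairs driven by a common
#'   latent factor (default 5).
#' @param n_background_signatures Random gene sets over unassigned genes
#'   (default 200).
#' @param group_shift Latent-activity shift applied to designated factors
#'   in group B of a two-condition dataset (default 0).
#' @param seed Integer root seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_datasets = 4L, n_genes = 5000L,
                           n_samples = 100L, n_planted_modules = 20L,
                           module_size = 50L, loading_scale = 1,
                           noise_sd = 1, n_conserved = 10L,
                           n_redundant_pairs = 5L,
                           n_background_signatures = 200L,
                           group_shift = 0, seed = 1L) {
  spec <- list(n_datasets = as.integer(n_datasets),
               n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               n_planted_modules = as.integer(n_planted_modules),
               module_size = as.integer(module_size),
               loading_scale = loading_scale, noise_sd = noise_sd,
               n_conserved = as.integer(n_conserved),
               n_redundant_pairs = as.integer(n_redundant_pairs),
               n_background_signatures = as.integer(n_background_signatures),
               group_shift = group_shift, seed = as.integer(seed))
  if (any(unlist(spec[c("n_datasets", "n_genes", "n_samples")]) < 1L))
    stop_("n_datasets, n_genes, n_samples must be >= 1")
  if (spec$module_size < 2L) stop_("module_size must be >= 2")
  if (spec$n_conserved > spec$n_planted_modules)
    stop_("n_conserved cannot exceed n_planted_modules")
  if (spec$group_shift < 0) stop_("group_shift must be >= 0")
  demand <- (spec$n_planted_modules + 2L * spec$n_redundant_pairs) *
    spec$module_size
  if (demand > spec$n_genes)
    stop_("planted gene demand (", demand, ") exceeds n_genes (",
          spec$n_genes, ")")
  if (spec$n_background_signatures > 0L &&
      spec$n_genes - demand < spec$module_size)
    stop_("not enough unassigned genes for background signatures")
  structure(spec, class = "synthetic_spec")
}

# +/- loading_scale loadings with random signs; flipped so the mean
# loading is positive (the overall sign of a factor is arbitrary, and a
# positive mean makes the oriented metasample track +activity, giving
# shifted factors a positive expected fold change).
draw_loadings <- function(m, loading_scale) {
  w <- loading_scale * sample(c(-1, 1), m, replace = TRUE)
  if (sum(w) < 0) w <- -w
  if (sum(w) == 0 && m > 0) w[1] <- abs(w[1])
  w
}

# Shared planted layout: gene blocks and factor assignment.
plant_layout <- function(spec) {
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  pos <- 0L
  take <- function(k) {
    blk <- genes[(pos + 1L):(pos + k)]
    pos <<- pos + k
    blk
  }
  modules <- lapply(seq_len(spec$n_planted_modules), function(i)
    take(spec$module_size))
  names(modules) <- sprintf("MODULE_%02d", seq_len(spec$n_planted_modules))
  pairs <- list()
  if (spec$n_redundant_pairs > 0L) {
    for (i in seq_len(spec$n_redundant_pairs)) {
      pairs[[sprintf("REDUNDANT_%02dA", i)]] <- take(spec$module_size)
      pairs[[sprintf("REDUNDANT_%02dB", i)]] <- take(spec$module_size)
    }
  }
  list(genes = genes, modules = modules, pairs = pairs,
       free = if (pos < spec$n_genes) genes[(pos + 1L):spec$n_genes]
              else character(0))
}

#' Generate a synthetic compendium with planted structure
#'
#' See [synthetic_spec()] for the generative model. Deterministic given
#' `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `datasets` (list of `expression_dataset`),
#'   `collection` (`signature_collection`: planted modules, redundant
#'   pair members, background signatures) and `truth` (data frame:
#'   `signature`, `planted`, `conserved_planted`, `redundant_partner`,
#'   `latent_factor_id`).
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- with_seed(derive_seed(spec$seed, "layout"), plant_layout(spec))
  n_fac <- spec$n_planted_modules + spec$n_redundant_pairs
  ## factor id per gene set
  fac_of <- c(seq_len(spec$n_planted_modules),
              rep(spec$n_planted_modules + seq_len(spec$n_redundant_pairs),
                  each = 2L))
  sets <- c(lay$modules, lay$pairs)
  conserved_names <- names(lay$modules)[seq_len(spec$n_conserved)]
  ## loadings reused across datasets for conserved modules
  w_cons <- with_seed(derive_seed(spec$seed, "conserved-loadings"),
    lapply(conserved_names, function(nm)
      draw_loadings(spec$module_size, spec$loading_scale)))
  names(w_cons) <- conserved_names
  datasets <- lapply(seq_len(spec$n_datasets), function(d) {
    id <- paste0("D", d)
    with_seed(derive_seed(spec$seed, "dataset", d), {
      X <- matrix(stats::rnorm(spec$n_genes * spec$n_samples,
                               sd = spec$noise_sd),
                  nrow = spec$n_genes,
                  dimnames = list(lay$genes,
                                  paste0(id, "_s",
                                         seq_len(spec$n_samples))))
      A <- matrix(stats::rnorm(n_fac * spec$n_samples), nrow = n_fac)
      for (k in seq_along(sets)) {
        nm <- names(sets)[k]
        w <- if (nm %in% conserved_names) w_cons[[nm]] else
          draw_loadings(spec$module_size, spec$loading_scale)
        X[sets[[k]], ] <- X[sets[[k]], ] + outer(w, A[fac_of[k], ])
      }
      expression_dataset(X, id)
    })
  })
  collection <- with_seed(derive_seed(spec$seed, "background"), {
    sigs <- lapply(names(lay$modules), function(nm)
      gene_signature(nm, lay$modules[[nm]], category = "planted"))
    sigs <- c(sigs, lapply(names(lay$pairs), function(nm)
      gene_signature(nm, lay$pairs[[nm]], category = "redundant")))
    if (spec$n_background_signatures > 0L)
      sigs <- c(sigs, lapply(seq_len(spec$n_background_signatures),
        function(i) gene_signature(sprintf("BACKGROUND_%03d", i),
                                   sample(lay$free, spec$module_size),
                                   category = "background")))
    signature_collection(sigs)
  })
  nms <- names(collection$signatures)
  partner <- rep(NA_character_, length(nms))
  is_pair <- startsWith(nms, "REDUNDANT_")
  partner[is_pair] <- paste0(substr(nms[is_pair], 1L, 12L),
                             ifelse(endsWith(nms[is_pair], "A"), "B", "A"))
  ## collection order is modules, pairs, background, matching c(fac_of, NA...)
  truth <- data.frame(
    signature = nms,
    planted = nms %in% names(sets),
    conserved_planted = nms %in% conserved_names,
    redundant_partner = partner,
    latent_factor_id = c(fac_of,
                         rep(NA_integer_, spec$n_background_signatures)),
    stringsAsFactors = FALSE)
  list(datasets = datasets, collection = collection, truth = truth)
}

#' Generate a structureless null compendium
#'
#' i.i.d. standard normal values, no correlation structure — the
#' substrate for estimating the selection procedure's FDR.
#'
#' @param n_datasets,n_genes,n_samples Dimensions.
#' @param seed Integer seed.
#' @return List of `expression_dataset` objects (`D1`, `D2`, ...).
#' @export
generate_null_compendium <- function(n_datasets, n_genes, n_samples, seed) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  lapply(seq_len(n_datasets), function(d) {
    id <- paste0("D", d)
    with_seed(derive_seed(seed, "null-dataset", d), {
      X <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                  dimnames = list(genes,
                                  paste0(id, "_s", seq_len(n_samples))))
      expression_dataset(X, id)
    })
  })
}

#' Generate one two-condition dataset
#'
#' One synthetic dataset whose samples are split 50/50 into groups A and
#' B; the latent activity of the designated planted modules' factors is
#' shifted by `group_shift` in group B. With the sign convention of
#' [generate_compendium()] (positive mean loading), a shifted module's
#' expected fold change (B - A) is positive.
#'
#' @param spec A `synthetic_spec` (its `n_datasets` is ignored; one
#'   dataset is produced).
#' @param group_shift Shift of the designated factors' activity in group
#'   B; defaults to `spec$group_shift`.
#' @param shift_modules Indices of planted modules whose factor is
#'   shifted (default 1).
#' @return List with `dataset` (`expression_dataset`), `groups`
#'   ([sample_groups()]), `collection`, and `truth` with a `shifted`
#'   column.
#' @export
generate_two_condition <- function(spec, group_shift = spec$group_shift,
                                   shift_modules = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (group_shift < 0) stop_("group_shift must be >= 0")
  if (spec$n_samples < 4L) stop_("need at least 4 samples for two groups")
  if (length(shift_modules) &&
      any(shift_modules < 1L | shift_modules > spec$n_planted_modules))
    stop_("shift_modules out of range")
  lay <- with_seed(derive_seed(spec$seed, "layout"), plant_layout(spec))
  n_fac <- spec$n_planted_modules + spec$n_redundant_pairs
  fac_of <- c(seq_len(spec$n_planted_modules),
              rep(spec$n_planted_modules + seq_len(spec$n_redundant_pairs),
                  each = 2L))
  sets <- c(lay$modules, lay$pairs)
  n_a <- spec$n_samples %/% 2L
  grp <- rep(c("A", "B"), c(n_a, spec$n_samples - n_a))
  ds <- with_seed(derive_seed(spec$seed, "two-condition"), {
    X <- matrix(stats::rnorm(spec$n_genes * spec$n_samples,
                             sd = spec$noise_sd),
                nrow = spec$n_genes,
                dimnames = list(lay$genes,
                                paste0("s", seq_len(spec$n_samples))))
    A <- matrix(stats::rnorm(n_fac * spec$n_samples), nrow = n_fac)
    A[shift_modules, grp == "B"] <- A[shift_modules, grp == "B"] + group_shift
    for (k in seq_along(sets)) {
      w <- draw_loadings(spec$module_size, spec$loading_scale)
      X[sets[[k]], ] <- X[sets[[k]], ] + outer(w, A[fac_of[k], ])
    }
    expression_dataset(X, "TWOCOND")
  })
  collection <- signature_collection(c(
    lapply(names(lay$modules), function(nm)
      gene_signature(nm, lay$modules[[nm]], category = "planted")),
    lapply(names(lay$pairs), function(nm)
      gene_signature(nm, lay$pairs[[nm]], category = "redundant"))))
  groups <- sample_groups(stats::setNames(grp, colnames(ds$values)), ds)
  truth <- data.frame(
    signature = names(sets),
    latent_factor_id = fac_of,
    shifted = fac_of %in% shift_modules & group_shift > 0,
    stringsAsFactors = FALSE)
  list(dataset = ds, groups = groups, collection = collection, truth = truth)
}
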