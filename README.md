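# infosig

Most gene-signature collections used to interpret transcriptomic data are
large, redundant, and full of sets that never behave as a coherent unit in
real expression data. `infosig` is an R package for prioritizing the
*informative* subset of a signature collection across a multi-dataset
expression compendium, scoring how reproducible each signature's gene
weights are across datasets, quantifying compositional versus functional
redundancy between signatures, and organizing the result into a
redundancy network that can be colored with differential-activity scores.
It is aimed at computational biologists who work with GMT signature
collections (MSigDB-style) and genes × samples expression matrices.

## The method

For a signature with $m$ matched genes in a dataset of $n$ samples, PCA
is applied to the $n \times m$ submatrix (samples as observations,
per-gene centered). With covariance eigenvalues
$\lambda_1 \ge \lambda_2 \ge \dots$:

* $L_1 = \lambda_1 / \sum_i \lambda_i$ — **overdispersion**, the variance
  explained by the first principal component;
* $L_1/L_2 = \lambda_1/\lambda_2$ — **coordination**, the spectral gap.

Both are tested against random gene sets of equal size from the same
dataset (empirical upper-tail p-values with a +1 pseudo-count, nulls
shared per set size), BH-corrected per dataset and statistic. A signature
is **informative** when both adjusted p-values are < 0.05 in ≥ 2
datasets. The first eigenvector (*eigengene*, unit gene weights) and the
sample projections (*metasample*, the activity profile) feed the
downstream analyses:

* **conservation score** $= -\frac{1}{N}\sum\log_{10} p$ over pairwise
  eigengene correlations between datasets; conserved iff the geometric
  mean p < 10⁻⁶;
* **functional redundancy** of a signature pair = mean across datasets of
  $|r|$ between their metasamples, contrasted with the Jaccard index of
  their gene sets (hypergeometric overlap test);
* **network**: edge iff functional redundancy > 0.7, weight = mean of the
  two redundancy measures, dark/light edge class by overlap significance;
* **differential activity**: Student t-test + group-mean difference on
  the metasample between two sample groups, significant at p < 0.05.

The selection FDR is estimated with a null model of random signatures
that mimic the reference collection's size distribution and gene
multiplicities. A synthetic compendium generator with planted modules,
conserved loadings and disjoint-but-redundant pairs makes every stage
testable without any data download.

## Worked example

```r
library(infosig)
sim <- generate_compendium(synthetic_spec(seed = 42))   # 4 datasets, 5000 genes,
fit <- infosig(sim$collection, sim$datasets, seed = 42) # 230 signatures
print(fit)
#> infosig fit: 230 signatures scored in 4 dataset(s)
#>   informative: 30 (alpha = 0.05, k_min = 2)
#>   conserved:   10 of 230 classifiable (geometric-mean p < 1e-06)
#>   network:     30 nodes, 5 edges (functional redundancy > 0.7), 25 component(s)
```

The 30 informative calls are exactly the 20 planted modules plus the
10 members of the 5 planted redundant pairs; the 10 conserved signatures
are the modules generated with a shared loading vector. Per-dataset
scores:

```r
head(subset(activity_table(fit$activity), dataset == "D1" & padj_l1 < 0.05), 2)
#>   signature dataset n_matched        l1     l1l2        p_l1      p_l1l2     padj_l1   padj_l1l2
#> 1 MODULE_01      D1        50 0.5611215 22.81786 0.000999001 0.000999001 0.007659008 0.007659008
#> 2 MODULE_02      D1        50 0.4491532 13.61730 0.000999001 0.000999001 0.007659008 0.007659008
```

A planted module explains ~50% of its submatrix variance (random
50-gene sets: ~6%) with a 10–20× eigenvalue gap. The planted
disjoint-but-redundant pairs illustrate the key dissociation — high
functional redundancy at zero gene overlap:

```r
head(fit$edges[fit$edges$jaccard == 0 & fit$edges$functional_redundancy > 0.7,
               c("sig_a", "sig_b", "jaccard", "functional_redundancy")], 3)
#>             sig_a         sig_b jaccard functional_redundancy
#> 391 REDUNDANT_01A REDUNDANT_01B       0             0.9765329
#> 408 REDUNDANT_02A REDUNDANT_02B       0             0.9810615
#> 421 REDUNDANT_03A REDUNDANT_03B       0             0.9749286
```

`plot(fit)` draws the network (circle = conserved, square =
informative-only, size ∝ gene count, dark edges = significant overlap);
`export_graph(fit$graph, "map.graphml", "graphml")` hands it to
Cytoscape; `write_infosig(fit, "out/")` writes the full TSV/GraphML/JSON
bundle with a manifest. File-based workflows use
`run_pipeline("sigs.gmt", "expr_dir/", "out/")` or the CLI wrapper in
`inst/cli/infosig.R` (subcommands `run`, `fdr`, `simulate`, `diff`).

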