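---
title: "Informative gene signatures: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informative gene signatures: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene signatures — curated or data-derived gene sets — are the working
vocabulary of transcriptomic interpretation, but most collections are
heavily redundant and many member sets never behave as a coherent unit in
real data. `infosig` implements a selection procedure that keeps only the
signatures that act as a single, strong axis of variation across several
expression datasets, then quantifies how reproducible and how mutually
redundant the selected signatures are, and organizes them into a network.

## The statistics

For a signature $S$ with $m$ matched genes in a dataset of $n$ samples,
PCA is applied to the $n \times m$ expression submatrix (samples as
observations, genes as variables, per-gene mean-centered). With
eigenvalues $\lambda_1 \ge \lambda_2 \ge \dots$ of the sample covariance
(denominator $n-1$):

* **Overdispersion** $L_1 = \lambda_1 / \sum_i \lambda_i$, the variance
  fraction of the first principal component.
* **Coordination** $L_1/L_2 = \lambda_1 / \lambda_2$, the spectral gap. A
  rank-1 submatrix ($\lambda_2 = 0$) is maximally coordinated and is
  represented by an `Inf` sentinel, which by construction receives the
  smallest attainable empirical p-value.

The first eigenvector is the signature's **eigengene** (unit-norm gene
weights); the centered samples projected on it form the **metasample**,
the per-sample activity profile. Both statistics are compared against
random gene sets of the same size drawn from the same dataset: the
empirical upper-tail p-value with a +1 pseudo-count,
$p = (1 + \#\{T_{null} \ge T_{obs}\})/(n_{draws}+1)$, is never zero,
which the BH step and the log-scale conservation score require. p-values
are BH-adjusted per dataset, separately for the $L_1$ and the $L_1/L_2$
family. A signature is **informative** when both adjusted p-values fall
below $\alpha = 0.05$ in at least $k_{min} = 2$ datasets. The source
texts state the dataset rule both as "at least two" and as "more than
two"; this package adopts $\ge 2$ (configurable), consistent with
treating signatures significant in exactly two datasets as the
cancer-specific tail of the selection.

### Why `n_draws` defaults to 1000

The empirical estimator has resolution $1/(n_{draws}+1)$. After BH
adjustment across $M$ scored signatures of which $k$ are true signals,
the smallest attainable adjusted p-value is roughly
$\frac{1}{n_{draws}+1}\cdot\frac{M}{k}$. At 100 draws this exceeds 0.05
whenever signals make up less than about a fifth of the collection — the
procedure could then never select anything at $\alpha = 0.05$ regardless
of effect size. 1000 draws push the floor two orders of magnitude below
the threshold for realistic signal fractions while remaining tractable,
because nulls are computed once per (dataset, set size) and shared by all
signatures of that matched size. The FDR null model (`estimate_fdr`)
keeps 100 draws per null: it only asks whether anything at all crosses
the threshold under a no-signal compendium, where resolution is
irrelevant, and it must cover many distinct set sizes.

### Sign conventions

The sign of a principal component is arbitrary. Everywhere a sign could
leak into a result, a deterministic rule is applied:

* eigengene/metasample orientation: the metasample is made to correlate
  non-negatively with the mean centered expression of the matched genes;
  exact ties are broken by making the largest-magnitude loading positive;
* eigengene conservation and functional redundancy use absolute Pearson
  correlations, so per-dataset sign flips cannot change any score.

## Conservation across datasets

For each signature scored in several datasets, the eigengenes of every
dataset pair are correlated over their shared genes (pairs with fewer
than `min_overlap = 10` shared genes are skipped; the per-pair two-sided
p-value comes from the $t$ transform of $|r|$ with $n-2$ df, floored at
$10^{-300}$). The conservation score is
$-\tfrac{1}{N}\sum \log_{10} p_{pair}$, the absolute log10 of the
geometric mean p-value over the $N$ retained pairs; a signature is
**conserved** when that geometric mean is strictly below $10^{-6}$
(score > 6). Base 10 is used so the threshold reads directly on the
p-value scale.

## Redundancy and the network

Two signatures can read out the same biological program with little or no
gene overlap. The package therefore measures redundancy twice:

* **compositional**: Jaccard index of the gene sets, with a one-sided
  hypergeometric overlap test (universe = all genes in the analyzed
  collection), BH-corrected across all evaluated pairs at $\alpha=0.05$;
* **functional**: mean across shared datasets of the absolute Pearson
  correlation between the two metasamples (datasets where either
  signature is unscored are excluded; pairs with fewer than
  `min_shared_datasets = 2` evaluable datasets are dropped).

The redundancy network connects two signatures when functional redundancy
strictly exceeds `edge_threshold = 0.7`; the edge weight is the plain
mean of the two redundancy measures (the averaging weights were an open
choice; equal weights are used and configurable), and the edge class
records whether the overlap is also significant (`functional-plus-JI`
vs `functional-only`). Node attributes carry the map semantics —
category, informative (diamond vs circle in the original rendering;
square vs circle in the base-graphics `plot` method), conserved, and
gene-set size. Layout is deliberately not computed: exports (GraphML,
SIF, JSON) delegate it to Cytoscape-class viewers.

## Differential activity

Between two sample groups, each signature's metasample (PCA fit on all
samples pooled, so both groups share one component) is compared with a
pooled-variance Student t-test; "fold change" is the difference of group
means, because centered PC projections have no meaningful ratio. The raw
$p < 0.05$ cut is kept (no correction across signatures at this step),
matching standard practice for coloring a signature map; a Welch variant
sits behind `var_equal = FALSE`. Degenerate inputs are defined rather
than left to chance: zero pooled variance with equal means gives
$t = 0, p = 1$; with unequal means, $t = \pm\infty$ and the $10^{-300}$
p floor.

## The synthetic compendium

`generate_compendium` emulates the statistical structure the method
assumes, not the marginal distributions of any real platform. The model
is a Gaussian latent-factor model: each planted module is a block of
`module_size` genes tied to one factor with per-sample activity
$a \sim N(0,1)$; gene values are $w_g\,a_s + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, with loadings of magnitude
`loading_scale` and random signs (flipped so the mean loading is
positive, making the expected fold change of a shifted factor positive —
the factor's overall sign is arbitrary). Conserved modules reuse one
loading vector across datasets; redundant pairs are two disjoint gene
blocks on one factor; background signatures are random sets of unassigned
pure-noise genes. Under this model the top covariance eigenvalue of a
planted module is $\approx m\,w^2 + \sigma^2$ (checked in the tests), so
the defaults — 4 datasets, 5000 genes, 100 samples, 20 modules of 50
genes, `loading_scale = 1`, `noise_sd = 1`, 10 conserved modules, 5
redundant pairs, 200 background signatures — give $\lambda_1 \approx 51$
against a noise edge near 3: a strong but not degenerate planted axis,
detectable at desk scale. These sizes mirror a small multi-cancer
compendium (a few datasets of ~100 samples; signatures of tens of genes).

What the generator does **not** model: count noise and mean–variance
coupling of RNA-seq, batch effects, heavy-tailed expression, gene–gene
correlation outside planted modules, and overlapping module memberships.
Passing tests on this substrate therefore demonstrate the statistical
machinery (selection calibration, FDR control, conservation and
redundancy contrasts), not robustness to real-data artifacts.

## Numerical choices

* PCA runs on the smaller Gram side ($m \times m$ or $n \times n$), so
  scoring thousands of random sets is cheap; eigenvalues are clipped at 0.
* All randomness flows from one root seed; per-dataset and per-set-size
  streams are derived by hashing stage tags, so any stage is reproducible
  in isolation and full pipeline reruns are byte-identical.
* Boundary conventions are strict where a threshold is stated as strict:
  functional redundancy exactly 0.7 draws no edge; a geometric-mean p of
  exactly $10^{-6}$ is not conserved.
* Expression matrices with missing values are rejected, not imputed, and
  gene identifiers match case-sensitively with no alias resolution —
  silent data surgery upstream of a variance statistic is worse than an
  error.

## Problem sizes used in validation

The test suite validates the pipeline end to end on the default synthetic
preset above, estimates the null-model FDR on 1000 random signatures over
a 4-dataset, 5000-gene, 100-sample i.i.d. Gaussian compendium
(`n_draws = 100` shared per size), contrasts conservation on 20
shared-loading vs 20 redrawn-loading modules, and checks differential
calibration on 150 module-level tests across three replicate
two-condition datasets. These sizes were chosen as the smallest at which
the binomial/rank-sum tolerances of the respective checks are meaningful.

## Limitations

* Single-component activity only: a signature spanning two independent
  programs is summarized by its dominant axis.
* Empirical p-values are tied at the grid $1/(n_{draws}+1)$; rank
  information beyond the null range is discarded by design.
* The hypergeometric overlap test treats the collection's gene universe
  as exchangeable, ignoring gene-wise selection biases of curated sets.
* The ≥ `k_min` rule treats datasets symmetrically; no weighting by
  sample size.
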