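---
title: "Gene interaction perturbation networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene interaction perturbation networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipni)
```

## The model

Co-expressed, physically interacting genes maintain a stable relative
ordering of expression in healthy tissue. This package quantifies how far a
tumor sample departs from that stability, one interaction edge at a time.

Expression values are first converted to relative ranks within each sample
(rank 1 = lowest expression, average ranks for ties). Ranks, rather than
absolute values, are used because they are robust to platform scaling,
library-size effects and much of batch variation, so cohorts profiled on
different platforms remain comparable. For an edge $(i, j)$ of a background
interaction network and a sample $s$, the perturbation is

$$p_s(i,j) \;=\; \bigl[r_s(i) - r_s(j)\bigr]\;-\;\bigl[r_{\mathrm{ref}}(i) - r_{\mathrm{ref}}(j)\bigr],$$

where $r_{\mathrm{ref}}$ ranks genes by their mean expression across a
cohort of normal reference samples. A sample whose expression ordering
equals the reference ordering has $p_s \equiv 0$ on every edge; entries are
bounded by $2(G-1)$ in magnitude; swapping an edge's endpoints flips every
sign. The edges-by-samples matrix of these deviations — the edge
perturbation matrix — is the central object: everything downstream
(perturbation scores, subtype discovery, survival gene screening) consumes
it or the genes it implicates.

Three conventions are worth stating because the underlying idea admits
variants:

* **Signed storage, magnitude analysis.** The matrix keeps the sign of each
  deviation, but the per-sample summary score
  $\log_2(\overline{|p_s|} + 1)$ and the tumor-versus-normal edge tests use
  $|p|$. Magnitude is the interpretable quantity ("how disrupted is this
  interaction"); sign is retained for downstream uses that care about
  direction. The $+1$ makes a reference-identical sample score exactly 0.
* **Shared gene universe.** Ranks are recomputed within the intersection of
  network genes with genes present in the reference and in every analyzed
  cohort, so rank differences are comparable everywhere; edges falling
  outside are dropped with a reported count.
* **Deterministic reference.** Ties in the reference means are broken
  lexicographically by gene identifier, so the reference benchmark is a
  reproducible permutation of $1..G$.

## The synthetic cohort generator

No external cohorts are downloaded; a generator supplies data with exactly
the statistical structure the method assumes, so every pipeline stage is
testable and the package's reference conditions are explicit.

Gene $g$ has a latent mean $\mu_g$ taken from a fixed decreasing sequence
(12 down to 2 on the log2(TPM+1) scale); a sample's value is
$\mu_g + N(0, \sigma^2)$ with $\sigma = 1$ by default. Normal samples are
exactly this, so the normal rank ordering is stable in expectation — the
premise of the reference benchmark. Tumor samples receive latent shifts of
two kinds:

* **Subtype shifts.** A fraction of edges (default 10% of 600) are sampled
  as *anchors*; one endpoint of each anchor is moved by `perturb_shift`
  (default 3, about 60 rank positions at the default gene spacing) with a
  sign drawn per subtype. The sign patterns give the default three subtypes
  their recoverable structure.
* **Prognostic shifts.** A small set of genes (default 10) moves in a fixed
  direction, scaled by a per-sample severity factor $\gamma_s \sim
  \mathrm{Unif}(0.5, 1.5)$. Survival is exponential with log-hazard
  `hazard_beta` (default 1.5) per standard deviation of $\gamma$, so
  perturbation burden drives outcome continuously. Subtype shifts alone
  could not do this: their signs cancel across subtypes in any pooled
  regression, which is why the generator separates the two mechanisms.

Because planting acts on latent means, a shifted gene perturbs *every*
network edge incident to it — the perturbation propagates through the real
pipeline instead of being written into its output. The generator's truth
therefore records the full incident edge set as perturbed (the anchors are
kept separately). Censoring times are uniform on $(0, \tau)$ with $\tau$
calibrated by bisection so the realized censoring fraction matches
`censor_rate` (default 30%).

The toy single-cell generator draws negative-binomial counts (dispersion 2,
expected library ≈ 3000 over 1000 genes, ≈ 8% mitochondrial) for two
epithelial clusters plus a background cluster, plants log2 fold changes of
2 on chosen genes, and converts a configurable fraction of cells into QC
violators (low features, low counts, high counts, high mitochondrial
fraction). At 1000 genes no cell can exceed the 6000-feature ceiling, so
that bound is exercised in unit tests with custom thresholds rather than by
the generator. What the generator does **not** emulate: ambient RNA,
doublets, batch effects, copy-number structure, and realistic dropout
patterns — passing tests show the statistics behave as specified, not that
they are robust to every artifact of real droplet data.

## Downstream stages and their defaults

**Single-cell QC and differential expression.** QC bounds default to
200–6000 detected genes, 500–40000 counts, ≤ 20% mitochondrial; all bounds
inclusive, since "min/max" phrasing implies closed intervals. Counts are
scaled to 10,000 per cell and log1p-transformed. Malignant-versus-benign
markers come from a two-sided Wilcoxon rank-sum test with
$|\log_2 FC| > 0.25$, BH $q < 0.05$; bulk tumor-versus-normal uses the same
test at $|\log_2 FC| > 0.5$. The rank-sum test is used for bulk DE as well
(rather than a moderated linear model) for distribution-robustness and zero
fitted hyperparameters — a deliberate simplification. The single-cell/bulk
intersection requires *sign-concordant* dysregulation, the strict reading
of "consistently dysregulated". Cell clustering, embedding and annotation
are not reimplemented: cluster labels are inputs.

**Consensus subtyping.** Monti-style resampling (default 200 resamples of
80% of tumor samples) with partitioning-around-medoids on a
$1 - \rho_{\mathrm{Spearman}}$ distance over edge features — Spearman
because perturbation values are rank-derived and heavy-tailed. Consensus
entries are co-assignment counts normalized by co-sampling counts. The
cluster number is chosen from the areas under the consensus CDFs: the
optimal $k$ is the last one whose successor adds less than 10% relative
area (so the elbow itself, not the flat region beyond it, is selected).
Final labels come from average-linkage hierarchical clustering of
$1 - \mathrm{consensus}$.

**Survival gene screening.** Per-gene univariate Cox fits (Efron ties) on
z-scaled expression in each cohort; Fisher's method combines the p-values
($X = -2\sum \ln p \sim \chi^2_{2k}$); a gene is kept when the meta-p is
below 0.05 *and* the coefficient signs agree across cohorts. The
concordance requirement avoids sign-conflicted genes and can be switched
off.

**Model benchmarking.** The two-stage framework crosses feature selectors
(stepwise Cox by AIC from the null model, cross-validated L1 Cox, random
survival forest importance, componentwise likelihood boosting) with
survival learners (stepwise Cox, L1, L2, elastic-net over
$\alpha \in \{0.1,\dots,0.9\}$, random survival forest, gradient-boosted
Cox, supervised principal components, partial-least-squares Cox). Each pair
is fit on the training cohort only and evaluated by Harrell's C-index on
every cohort; records are ranked by the mean. Both registries are plain
named lists and fully configurable; a survival support-vector machine is
not included in the defaults. The concordance index and the IPCW
cumulative/dynamic time-dependent AUC are implemented directly from their
defining pair counts and verified against brute-force enumeration oracles
and the survival package.

**Risk stratification.** The final signature is a linear predictor
$\sum_g \beta_g z_g$. The cutpoint search evaluates every observed score
between the 10% and 90% quantiles and minimizes the two-group log-rank p,
breaking ties toward the median. The minimal p is reported *as found*: the
search over cutpoints inflates it, which is standard practice for this kind
of stratification and is why it should be read as descriptive, not
inferential.

**Enrichment.** ssGSEA follows the rank-weighted ECDF-difference walk with
$\alpha = 0.25$ and matrix-wide min–max normalization. A set covering every
gene has no out-of-set ECDF and degenerates to a constant (0). Associations
with the risk index use Spearman correlation with BH adjustment across
sets. The packaged 28-panel immune GMT carries synthetic placeholder
markers (it exists so the stage is exercisable offline); real marker panels
are user-supplied.

## Numerical and degenerate-input choices

* z-scaling uses the sample (n−1) standard deviation; constant genes map to
  zero rows and are flagged; single-sample cohorts are an error.
* Duplicate network edges keep the maximum confidence; duplicate expression
  rows collapse by per-sample maximum; STRING-style 0–999 scores are
  divided by 1000.
* Fisher meta-p clamps p = 0 inputs to 1e-300 with a warning.
* Cox non-convergence flags the gene with p = 1 rather than failing the
  screen; the multivariate fit, by contrast, fails loudly because its
  output feeds directly into reported hazard ratios.
* All stochastic operations take explicit seeds (default 17) and are
  bit-reproducible under a fixed seed and configuration.

## Problem sizes used in the test suite

The packaged reference conditions are deliberately desk-scale: 200 genes,
600 edges, two cohorts of 50 tumors plus 50 normals, 1100 single cells.
At these sizes the full pipeline — generation, perturbation, consensus
clustering, screening, benchmarking and evaluation — runs in seconds, and
the planted structure is recovered with wide margins (edge-recovery AUROC
above 0.9, consensus $k = 3$, cross-cohort C-index above 0.65). These are
properties of the generator's conditions, not claims about any particular
clinical cohort.

## Known limitations

* The published 11-gene signature ships with its gene list only; the
  published coefficients are not numerically recoverable, so scoring
  requires retraining on the user's cohort.
* The minimal-p cutpoint and the unadjusted benchmark ranking both carry
  selection optimism; external validation is the only honest check.
* The rank statistic ignores expression magnitude entirely; an edge between
  two barely expressed genes can look as perturbed as one between abundant
  genes.
* Consensus clustering inherits the usual sensitivity to the resampling
  fraction and inner algorithm; the defaults here are explicit substitutes
  for unstated upstream choices, exposed as parameters rather than baked
  in.
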