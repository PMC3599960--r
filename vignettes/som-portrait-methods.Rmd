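---
title: "Methods behind SOM expression portraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind SOM expression portraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somportraits)
```

somportraits turns a genes-by-samples expression matrix into
sample-specific "portraits": mosaic images of a self-organizing map (SOM)
whose tiles are metagenes, prototype expression profiles each representing
a minicluster of co-expressed genes. Downstream, the package scores
differential expression per gene and sample, estimates false discovery
rates, compares the resulting rankings, and interprets spot clusters with
gene-set overrepresentation and enrichment statistics. This vignette
explains the models, the tunable parameters and the numerical choices, and
states what the synthetic validation does and does not demonstrate.

## Input model and preprocessing

The pipeline consumes positive linear-scale expression values
$E_{g,m,r}$ for gene $g$, condition $m$ and replicate $r$ (data that are
already log10 can be declared with `scale = "log10"`). Preprocessing is:

1. quantile normalization of the logged sample columns (average-rank tie
   handling, so the operation is deterministic and idempotent);
2. replicate averaging, $e_{g,m} = \langle \log_{10} E_{g,m,r}\rangle_r$,
   retaining the population-form replicate SD
   $\sigma_{g,m} = \sqrt{\langle (e_r - \langle e\rangle)^2\rangle_r}$ for
   the error model;
3. gene centering, $\Delta e_{g,m} = e_{g,m} - \langle e_{g,m}\rangle_m$,
   so every gene's profile has zero mean across samples.

Whether normalization runs before or after replicate averaging is
configurable (`normalize = "before"/"after"/"none"`); the default
normalizes the individual sample columns first, since replicate columns
are separate measurements of the same condition and should be calibrated
individually.

## SOM training

The grid (default 60x60, so K = 3600 metagenes) is linearly initialized on
the plane of the two leading eigenvectors of the gene-profile covariance,
with tile coefficients spanning [-1, 1] in both grid directions. The
eigenvectors are scaled by the standard deviation along each component and
sign-fixed (largest-magnitude entry positive), which makes initialization
deterministic and platform-independent. Training then iterates single-gene
presentations: find the best-matching metagene by Euclidean distance (ties
resolved to the lowest row-major index), and move it and its neighbors
toward the gene profile by
`rate * exp(-d^2 / (2 sigma_i^2)) * (gene - metagene)`.

Schedule parameters, all configurable through `som_schedule()`:

* `presentations` (default 250,000): total single-gene updates. Genes are
  presented in a seeded shuffled cyclic sweep, so presentation counts are
  balanced and a fixed seed makes training bit-reproducible.
* learning rate: linear decay from 0.05 to 0.01.
* neighborhood radius: exponential decay from `kx / 2` to a final radius
  of 1.5 tiles. The non-vanishing final radius is deliberate: ending with
  a near-zero neighborhood lets prototypes specialize so aggressively that
  one tight co-expression cluster fragments over many tiles; keeping
  adjacent prototypes weakly coupled at the end makes clusters occupy
  compact grid regions, which is what spot detection relies on. Radius 0
  (pure competitive learning) remains available.

Empty metagenes (tiles that attract no genes) are legitimate and are
rendered white in all maps.

## Portraits, summary maps and spots

A sample's portrait colors each tile by its metagene value with a
two-segment linear scale: minimum to blue (0,0,255), arithmetic mean of
the unmasked tiles to green (0,128,0), maximum to maroon (128,0,0). The
scale is anchored per field, so affine transformations of the values do
not change the image; the per-sample anchoring (rather than a gallery-wide
scale) is the default because each portrait should use its full dynamic
range, and can be revisited by rendering fields jointly.

The overexpression summary map takes the per-tile maximum over samples
(minimum for underexpression). Spots are connected components of tiles
strictly beyond the 98% (or 2%) empirical quantile of the field,
with 8-neighbor connectivity — visually contiguous blobs include
diagonals — and type-1 (inverse-CDF) quantiles so the criterion is exactly
reproducible. Spots are labeled A, B, C... by decreasing peak deviation.
A spot's gene list is the union of its tiles' miniclusters.

## Differential expression scores

Three complementary per-gene, per-sample scores:

* **logFC** — the centered log10 expression $\Delta e_{g,m}$ itself.
* **WAD** — $\Delta e$ weighted by its relative position in the sample,
  $w = (\Delta e - \min)/(\max - \min)$; emphasizes strongly expressed
  genes whose signals are more reliable.
* **shrinkage t** — $t = \Delta e / SE$ with a shrunken error
  $\sigma^{shr} = \sqrt{\lambda\,\sigma^2 + (1-\lambda)\,\sigma_{LPE}^2}$.
  $\sigma_{LPE}(e)$ is the locally pooled error: replicate SDs averaged
  over a moving window of `W = 200` genes in expression order (step
  interpolation, no smoothing, for reproducibility). The default
  $\lambda = 0.5$ balances the gene-specific SD (unbiased but noisy with
  few replicates) against the pooled curve (stable but blind to
  gene-specific variance); both endpoints are meaningful: $\lambda = 1$
  is the naive t, $\lambda = 0$ the pure pooled-error score.

The standard error defaults to the approximate form
$\sigma^{shr}/\sqrt{R_m}$; the exact form adds the variance of the gene's
grand mean, $\langle\sigma^{shr\,2}\rangle_m / \sum_m R_m$, and is
available with `se_mode = "exact"`. Two-sided p-values use a Student t
with $R_m - 1$ degrees of freedom; conditions with a single replicate
carry no per-gene SD, so they borrow the pooled curve of the
best-replicated condition and use a normal approximation. These are
deliberate approximations: the p-values are mildly conservative (centering
against the grand mean shrinks $\Delta e$ by a factor $\sqrt{1 - 1/M}$,
and the shrunken SE has more effective degrees of freedom than $R_m - 1$),
which the null-data tests quantify rather than hide.

## fdr / Fdr estimation

The p-value density is modeled as
$\rho(p) = \eta_0 \rho_0(p) + (1-\eta_0)\rho_{DE}(p)$ with uniform
$\rho_0$ and a decaying alternative that vanishes at $p = 1$, so
$\rho(1) = \eta_0$ and the fraction of differentially expressed genes is
$\%DE = 1 - \eta_0$. `estimate_fdr()` fits a monotone non-increasing
density by isotonic regression of equal-width histogram densities
(weighted pool-adjacent-violators) — the binned form of the Grenander
estimator. Binning matters at the boundary: the unbinned least concave
majorant of the ECDF has slope zero beyond the largest observed p-value,
so the literal slope at p = 1 would be degenerate; with up to 100 bins the
estimate at p = 1 is well behaved (mean absolute error around 0.04 for
$\eta_0 \in \{0.5, 0.7, 0.9\}$ at n = 10,000 in the test suite).
By construction $fdr(p) = \min(1, \eta_0/\hat\rho(p))$ is exactly 1 at
p = 1, $Fdr(p) = \eta_0 p / \hat F(p)$ equals $\eta_0$ at p = 1 and
$fdr(0)$ at p = 0, and $Fdr \le fdr$ wherever $\hat\rho$ decreases.

## Comparing ranked lists

Rankings are by descending score magnitude with lexicographic gene-id
tie-breaking. `cat_curve()` reports the correspondence at the top,
$CAT(r) = |top_r(A) \cap top_r(B)|/r$, against the null expectation
$r/N$ of independent rankings. `p_cat()` accumulates log10 p-values
(base 10 chosen to match the package's log scale) of the top-r genes;
the t-ordered list is pointwise optimal, so
$\Delta pCAT = pCAT_{alt} - pCAT_t \ge 0$ quantifies how much significance
an alternative ordering sacrifices. `rank_correspondence()` flags
positions whose rank in the other list moves by more than a window
(default 20 positions, a plotting convention, not a method constant).

## Gene-set statistics

**Overrepresentation** uses the hypergeometric tail
$p = P(X > N_+)$ for an overlap of $N_+$ between a list of $N_{list}$
genes and a set of $N_{set}$ genes in a universe of $N$. The
strictly-greater tail is the package's printed convention; most external
tools use the inclusive tail $P(X \ge N_+)$, available via
`tail = "inclusive"`.

**Enrichment** uses the regularized gene-set Z-score. With
$\Delta S = S^+ - S^-$ (list scores summed over set members minus
non-members),

$$GSZ = \frac{\Delta S - E[\Delta S]}
{\sqrt{\lambda\,SE^2 + (1-\lambda)\,SE_0^2}},$$

where $E[\Delta S] = \langle S\rangle (2 E[N_+] - N_{list})$ and the
exact null variance over random sets is

$$SE^2 = 4\left(\frac{var(S)}{N_{list}-1}\bigl(E[N_+](N_{list}-E[N_+]) -
var(N_+)\bigr) + \langle S\rangle^2 var(N_+)\right)$$

with hypergeometric moments of $N_+$ and the population (divide-by-N)
variance of the scores. This is the exact sampling-without-replacement
variance; for unit scores it collapses *exactly* to the
overrepresentation Z-score $(N_+ - E[N_+])/\sqrt{var(N_+)}$
(`gsz_binary()`). For the full list ($N_{list} = N$) the
overexpression Z-score
$(\langle S\rangle_{set} - \langle S\rangle)/\sqrt{var(S)/N_{set}}$
(`gsz_full_list()`) is a large-N simplification rather than an exact
reduction: it drops the finite-population factor $(N - N_{set})/(N - 1)$,
so the two agree only asymptotically (ratio
$\sqrt{(N-1)/(N-N_{set})}$). The package keeps the exact variance in
`gsz()` and the conventional closed form in `gsz_full_list()`, and its
test suite records the discrepancy explicitly instead of silently
aligning them.

Regularization penalizes short lists and small sets:
$\lambda = 1 - \min(1, (N^{min}_{list}/N_{list})(N^{min}_{set}/N_{set}))$
with defaults $N^{min} = 10$, and $SE_0^2$ is the large-N variance
evaluated at the minimum sizes. Significance comes from a seeded
permutation null of size-matched random sets (default B = 1000, add-one
estimator, one- or two-tailed). Across a collection,
Benjamini-Hochberg-adjusted p-values are reported alongside raw ones.

Contexts: per-metagene overrepresentation maps (sample-independent, tiles
without set members masked white), per-spot enrichment (HG p plus
sample-specific GSZ), per-set overexpression profiles across samples with
a permutation-derived fdr = 0.2 threshold line, and a top-three
aggregation heatmap (union of each context's three most significant sets,
-log10 p, rows ordered by average-linkage hierarchical clustering of
Euclidean distances — a documented choice, as no canonical linkage
exists for this display).

## Special gene sets

Global-criterion sets: the top decile by maximum differential expression
(highly expressed), the top decile by ascending rank product of
per-sample expression ranks (consistently top-ranked; geometric-mean rank
product, the standard definition), genes with present call 0 in every
sample (absent), present call 1 everywhere (housekeepers), and the top
decile by mean expression (alternative housekeepers). Spot-derived
tissue-specific sets keep only genes whose profile correlates with their
own metagene at Pearson r > 0.8; genes with constant profiles are
excluded because the correlation is undefined. Absence criteria based on
raw-intensity calibration curves are out of scope — such lists can be
supplied externally as GMT files.

## Synthetic data: what it emulates and what it does not

`generate_expression()` draws log10 baselines from N(2.5, 0.7) (about
three decades of dynamic range, as in microarray data), plants disjoint
modules of co-expressed genes upregulated by `effect` log10 units in
their active sample group, and adds replicate noise with SD
$\sigma_0 + slope \cdot \max(0, e_{knee} - e)$ (defaults 0.05, 0.15, 2.0)
so that noise inflates at low expression, as observed in log-scale
microarray error models. Present calls flag genes above a detection floor
(default 1.5). Everything is a pure function of the seed.

The generator does **not** emulate probe-level effects, batch effects,
correlated background genes, overlapping modules, or partially active
modules. Passing the planted-module recovery experiment therefore shows
that the machinery — training, mapping, quantile spot detection, list
extraction, enrichment ranking — is internally correct and
well-calibrated; it does not certify performance on real tissue panels,
where module boundaries are soft and background correlation is
substantial.

## Problem sizes and numerical choices

The validation suite runs deliberately scaled-down experiments chosen to
exercise every code path at desk scale: SOM grids of 8x8 to 20x20 with
8,000-60,000 presentations for module recovery (the 20x20 / 50,000
configuration recovers three planted 100-gene modules in a 5,000-gene,
12-sample cohort with Jaccard >= 0.9 in typical seeds), n = 10,000
p-values for fdr calibration, 1,000-permutation GSZ nulls reduced to
120-500 permutations in the faster checks. Degenerate inputs are handled
explicitly: constant expression states yield zero spots with a warning;
constant score columns make WAD undefined and error; zero standard errors
yield p = 1 at zero effect and p = 0 (with a warning) otherwise; empty
metagenes propagate as masked tiles rather than NaN.

## Known limitations

* Per-sample p-values inherit the approximations discussed above and are
  best read comparatively; on null synthetic data the estimated null
  fraction is typically 0.8-1.0 rather than exactly 1.
* The rank-product criterion uses the standard geometric-mean definition;
  implementations differing in tie handling will produce slightly
  different top deciles.
* The quantile spot criterion caps the total spot area at (1 - q) of the
  grid; tight budgets truncate gene lists of large clusters. The final
  training radius default mitigates this (see above), and q is
  configurable.
* Zoom-in analysis retrains on a sample subset with the same grid; its
  spots are not nested within the full run's spots by construction.
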