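---
title: "Methods behind milknet: networks, censored imputation and simultaneous components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind milknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milknet)
```

`milknet` analyses a label-free proteomics matrix (samples × proteins, LFQ
intensities) collected under a 2×2 design: maternal allergy (M+/M−) crossed
with child allergy development (C+/C−). This vignette explains the models
and the numerical choices, stage by stage, and states what the synthetic
generator does and does not emulate.

## Missing data model and imputation

Zeros in LFQ exports encode non-detection, not true zero abundance, so they
are mapped to missing at read time. Missingness is assumed *not at random*
and left-censored: the probability that a value is missing increases as the
true abundance falls towards the detection limit.

Proteins are first filtered by **group validity**: a protein is kept if it
has at least `min_valid` (default 25) observed values in at least one of
the four groups. Requiring validity in *some* group rather than overall
keeps proteins expressed in only one condition — precisely the ones a
differential analysis cares about.

Imputation operates on the log10 scale and is a truncated Gibbs scheme in
the spirit of censored-aware samplers:

* the truncation bound for protein $j$ is its observed minimum $b_j$
  (imputed values may not exceed what was ever observed);
* missing cells start at $0.9\,b_j$;
* per sweep, each incompletely observed protein is regressed on its
  `n_predictors` (default 20) most correlated peers with a closed-form
  ridge penalty (`ridge_lambda`, default 1), fitted on the rows where the
  protein was observed; its missing cells are redrawn from
  $\mathcal N(\hat y, \hat\sigma^2)$ truncated above at $b_j$;
* sweeping stops after `sweeps` (default 20) or when the mean relative
  change of imputed cells drops below $10^{-3}$; the completed matrix
  averages the last `average_last` (default 5) sweeps to damp Monte-Carlo
  noise.

Two contracts hold exactly and are asserted by the tests: observed cells
are never altered, and every imputed value respects its protein's bound.
The regression is fitted on observed rows only: fitting on the current
completed matrix lets early low imputations drag later predictions down, a
feedback loop that roughly doubled the imputation error in our development
benchmarks. A constant-minimum imputer (`impute_minimum()`) is provided as
the baseline against which accuracy is judged on synthetic truth.

## Univariate screening

Per protein, a tie-corrected Kruskal–Wallis test compares the four groups
(chi-square reference, 3 degrees of freedom), with Benjamini–Hochberg
correction across proteins. Proteins with *uncorrected* KW p < 0.05 move to
Dunn's post-hoc test for all six group pairs: on the jointly ranked data,

$$z_{ab} = \frac{\bar R_a - \bar R_b}
{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
\left(\frac{1}{n_a}+\frac{1}{n_b}\right)}}$$

with a two-sided normal p-value. The uncorrected gate is deliberately
liberal — multiple-testing correction at the screening stage is widely
considered too stringent for bottom-up proteomics, where each protein is
supported by several peptides. The BH family for the Dunn p-values pools
all (protein, pair) tests, the conservative reading; a per-protein family
is available via `family = "per_protein"`. Trend direction ("up"/"down")
uses group means of log10 abundance, matching the volcano summaries, which
report the ratio of group-mean log10 intensities per protein and per
annotation keyword.

## Multivariate exploration

PCA (`stats::prcomp`) runs on the unit-variance-scaled imputed matrix;
component signs are canonicalised (largest-magnitude loading positive) so
repeated runs are bit-identical. Random-forest classification uses
out-of-bag predictions as the internal validation — no extra
cross-validation scheme is invented — with accuracy, sensitivity,
specificity (the first factor level is the positive class) and AUROC from
OOB class-probability votes. Significance comes from label permutations:
the full forest is refitted per permutation under a derived seed and
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, which is bounded below
by $1/(B+1)$ and conservative under ties. Samples never out of bag (a
possibility with very small forests) are excluded from the metrics. Tree
count (default 500) and permutation count (default 1000) are recorded in
the pipeline manifest.

## PCLRC network inference

Associations within each group are Spearman correlations $r_{ij}$
(average-rank ties; a constant protein is rank-degenerate and gets zero
correlations with a warning). Raw correlation matrices contain substantial
nonspecific background, so each resample is corrected with a CLR-style
transform on $M = |r|$ with the diagonal excluded from row statistics:

$$z^{(i)}_{ij} = \max\!\left(0, \frac{M_{ij}-\mu_i}{\sigma_i}\right),
\qquad \mathrm{CLR}_{ij} = \sqrt{(z^{(i)}_{ij})^2 + (z^{(j)}_{ij})^2}.$$

Per iteration (default 1000), 75% of the group's samples are drawn without
replacement, and the top `keep_fraction` of upper-triangle edges by CLR
score are marked retained, ties broken deterministically by score then
index. The retention probability $p_{ij}$ is the retained fraction across
iterations; the network keeps the full-data Spearman weight (sign
included) where $p_{ij} \ge \tau$ (default 0.99, the equation-form
threshold; the strict form is one configuration flag away). Connectivity
is $\chi_i = (\sum_j |r_{ij}|) - 1$ with a unit diagonal cancelling the
self term, so on a binary network $\chi$ is the node degree.

`keep_fraction` (default 0.30, the published default of the resampling
method) deserves care: a fixed fraction of edges is retained *per
iteration regardless of how much true structure exists*. If the true edge
density is far below `keep_fraction`, the strongest background
correlations are retained persistently and survive the $\tau$ threshold;
our recovery experiments measure ~25% false edges in that regime, against
0–2% when the retention fraction is matched to the expected density. The
recovery suites therefore calibrate `keep_fraction` to the planted
density, which is how the parameter is meant to be used; on real data it
should be set from the expected connectivity, not left at 0.30 by reflex.
Note also that the CLR background correction deliberately suppresses edges
inside large equicorrelated cliques (they are not "surprising" given their
rows), so planted structure in the test suites uses many small blocks
rather than one large one.

Differential connectivity between two groups is
$\Delta_i = \chi_i^{(a)} - \chi_i^{(b)}$. Its significance uses a group
label permutation null: samples are pooled, group assignments permuted
preserving sizes, and both networks recomputed per permutation at a
reduced iteration budget (default 100) — the observed $\Delta$ is computed
at the same budget so observed and permuted statistics are exchangeable
under the null. Two-sided add-one p-values are BH-corrected across
proteins. Candidate proteins have $|\Delta|$ above `delta_threshold`
(default 50, appropriate for cohort-scale networks of ~700 proteins;
synthetic-scale examples use smaller thresholds), and the intersection
across the three comparisons against the doubly non-allergic reference
group is reported.

## COVSCA

The four group adjacency matrices are modelled simultaneously as

$$S_k \approx \sum_{l=1}^{L} c_{kl}\, Z_l Z_l^{\mathsf T}, \qquad
c_{kl} \ge 0,$$

with unit-norm prototype loadings $Z_l$ (rank 1 by default; orthonormal
columns for higher ranks). The fit alternates two exact subproblem solves:
the weights step is a small non-negative least squares over the prototype
Gram features, solved exactly by active-set enumeration (L is 2–4); the
loading step replaces $Z_l$ by the dominant eigenvectors of the weighted
residual aggregate. Both steps solve their subproblem exactly, so the
Frobenius objective is non-increasing — asserted per iteration in the
tests. Multi-start (default 20 random starts plus one spectral start from
the mean matrix) mitigates local minima; sign indeterminacy is removed by
canonicalisation, making the fit deterministic given the seed.

COVSCA consumes the PCLRC adjacency with absolute weights and a zeroed
diagonal: absolute weights keep the matrices close to positive
semidefinite and the zero diagonal prevents self-edges from dominating the
Frobenius objective. Goodness of fit is
$100\,(1 - \sum_k \|S_k - \hat S_k\|_F^2 / \sum_k \|S_k\|_F^2)$. Weights
$c_{k\cdot}$ place each group network as a point in component space;
loadings are z-scored per component and $|z| > 2$ flags the proteins
driving between-network differences.

## Overrepresentation

The enrichment stage is a two-list test: with $N$ background proteins, $K$
carrying a term, and a selection of $n$ proteins with overlap $k$, the
p-value is the upper hypergeometric tail $P(X \ge k)$, BH-corrected across
terms. Terms are flat labels from the annotation table; no ontology
hierarchy propagation is attempted, which keeps the test semantics exact
and self-contained.

## The synthetic generator

`generate_lfq_dataset()` draws protein-level log10 means from
$\mathcal N(6.0,\ 0.8^2)$ with within-protein spread 0.4 — typical orders
of magnitude for LFQ intensities — and plants structure through a Gaussian
copula on the latent log10 values:

* **blocks**: compound-symmetric correlation $\rho$ among consecutive
  proteins, active only in configured groups;
* **hubs**: a one-factor star (hub loading 0.95) giving hub–neighbour
  correlation $\rho$ and neighbour–neighbour correlation $(\rho/0.95)^2$,
  with per-group neighbour counts — the ground-truth differential hub;
* **shifts**: additive log10 offsets for keyword-tagged protein sets in one
  group (defaults: 83 immunoglobulin-tagged proteins in the M−/C+ group,
  77 shifted up and 6 down by 0.2);
* **censoring**: each cell goes missing with probability
  $\mathrm{logit}^{-1}((b_j - x)/s)$ where $b_j$ is the protein's
  `censor_quantile` quantile (default 0.3) and $s$ the softness (default
  0.05 log10 units). The sharp default models a detection limit whose
  transition spans ~12% relative intensity; a diffuse logistic would make
  the missing cells an even mixture of low and mid values, under which no
  left-censored imputation model (the package's included) is appropriate.

Default study conditions mirror the target design: four groups of 75
samples, 687 proteins, blocks that are denser in the groups where mother
and/or child are allergic, and one differential hub. The reference
adjacency (`generate_group_networks()`) records block cliques and
hub–neighbour edges; the weaker second-order neighbour–neighbour
correlations of the hub construction are treated as background.

What the generator does **not** emulate: peptide-level evidence and
roll-up, technical replicates and batch structure, intensity-dependent
variance, contaminants, or realistic correlation spectra of a full
proteome (block/hub defaults are chosen for testability). Passing recovery
suites therefore demonstrates correctness of the algorithms under the
stated model, not performance guarantees on cohort data.

## Problem sizes, seeds and degenerate inputs

Every randomised stage draws its seed from a master seed via a documented
tag (`derive_seed(seed, "pclrc/M+/C+")`), so a configuration plus one
integer reproduces every output byte-for-byte (`pipeline.log`, which
carries wall-clock timings, is the only exception). The test and
acceptance suites run the expensive stages at reduced but honest sizes
chosen once: PCLRC recovery at 41 proteins × 75 samples × 1000 iterations;
differential-connectivity inference at 30 proteins × 75 samples × 99
permutations (hub) and twenty 15-protein null replicates at 49
permutations; pipeline determinism at the full default conditions
(4×75 × 687) with reduced per-stage budgets, which determinism does not
depend on.

Degenerate inputs are handled explicitly: constant proteins are zeroed in
correlation matrices (warning) and rejected by the scaler (error);
fully missing proteins are rejected by the imputer with a pointer to the
validity filter; empty Dunn candidate sets and empty enrichment targets
return empty results rather than errors; `nnls_small` tolerates singular
active sets by skipping them; zero-variance COVSCA loading vectors are an
error in `loading_selection`.

## Known limitations

* The permutation null for differential connectivity is computationally
  heavy (two network inferences per permutation); the reduced iteration
  budget trades edge-probability resolution for runtime.
* The uncorrected Dunn gate propagates screening-stage false positives by
  design; users wanting strict FDR control should gate on adjusted KW
  p-values instead.
* COVSCA model order (L, ranks) is not selected automatically; fit a small
  grid and compare goodness of fit against model complexity.
* Enrichment treats annotation terms as flat labels; ontology-aware
  propagation is out of scope.
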