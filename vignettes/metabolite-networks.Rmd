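---
title: "Dual-method metabolite network analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-method metabolite network analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tryptnet)
```

## The scientific question

Urinary concentrations of tryptophan and its catabolites (kynurenine,
serotonin and indole pathways) are correlated through shared enzymes, shared
regulation and host–microbiome exchange. A pairwise association that is
*strong* and *temporally reproducible* — present at two measurement
occasions a year apart — is a better candidate for a stable metabolic
fingerprint than an association seen once. Because any single network
estimator can produce artifacts, this package demands *cross-method
consensus*: an association counts only if two structurally different
estimators, a Gaussian graphical model (GGM) and a linear-Gaussian Bayesian
network (BN), both call it strong at both timepoints. Analyses are
sex-stratified throughout, since tryptophan metabolism is sex-dependent.

The design emulated by the synthetic generator is a cohort of roughly 64
males and 68 females measured at a baseline and a follow-up visit, with 19
metabolite concentrations (µM) and five covariates: birth weight (g), birth
length (cm), BMI (kg/m²), energy intake (kcal/day) and protein intake
(g/day).

## Models

### Gaussian graphical model by graphical lasso

For standardized data with sample covariance $S$, the estimator maximizes

$$\log\det\Theta - \operatorname{tr}(S\Theta)
  - \lambda \sum_{i \neq j} |\Theta_{ij}|$$

over positive-definite precision matrices $\Theta$. Edges are the exact
nonzeros of $\Theta$; edge weights are regularized partial correlations
$\rho_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. The penalty
$\lambda$ is chosen on a descending log-spaced grid from
$\lambda_{\max} = \max_{i\neq j}|S_{ij}|$ (the empty-network threshold) down
to $\lambda_{\max}/100$, minimizing

$$\mathrm{IC}(\lambda) = -2\,\ell(\hat\Theta) + E\log n
  + 4\gamma E \log p ,$$

with $E$ the edge count and
$\ell = \tfrac{n}{2}(\log\det\Theta - \operatorname{tr}(S\Theta)) -
\tfrac{np}{2}\log 2\pi$. The default $\gamma = 0$ is the plain BIC; the
extended-BIC weight $\gamma = 0.5$ favoured by some graphical-model software
is available through the `gamma` argument, because the two conventions can
select different networks at these sample sizes and the choice should be
explicit and logged. Ties in the criterion go to the sparser fit (larger
$\lambda$).

### Linear-Gaussian Bayesian network by BIC hill climbing

Each node is a linear regression on its parents. The network score is

$$\sum_{v} \Big[ \log L_v(\text{parents}) -
  \tfrac{|\mathrm{pa}(v)| + 2}{2}\,\log n \Big],$$

with the maximum-likelihood residual variance and the intercept and variance
counted as parameters (centering makes the intercept numerically irrelevant
but it is still counted — the convention matters for reproducibility). This
score is likelihood-equivalent: Markov-equivalent DAGs score identically,
which is one reason arc *directions* are not interpreted downstream. Search
is plain greedy hill climbing from the empty graph over single-arc
additions, deletions and reversals, with deterministic lexicographic
tie-breaking on (operation, parent, child); no tabu list and no random
restarts by default (seeded restarts are available via `restarts`).

Uncertainty is handled by bootstrap model averaging: the structure is
re-learned on `B` row-resamples (default 1000) and each unordered pair's
*strength* is the fraction of resamples in which the pair is adjacent in
either orientation. Direction frequencies are recorded but deliberately
unused: at these sample sizes edge orientation from observational data is
unreliable, so only the undirected skeleton is interpreted.

### Strong edges, reproducibility, consensus

Strong edges are $|\rho| \geq 0.3$ for the GGM (inclusive — the published
reference lists count an edge at exactly 0.30, and a negative edge of
−0.31, as strong, so the cutoff applies to the absolute value) and
strength $\geq 0.85$ for the BN (inclusive: present in at least 85% of
resamples). Covariate adjustment means covariates enter as ordinary network
*nodes*; strong-edge extraction then keeps metabolite–metabolite pairs.
Edge identity is the unordered name pair; weights and signs are annotations,
and GGM sign flips between timepoints are flagged rather than breaking the
match. Temporal reproducibility is the intersection of the adjusted baseline
and follow-up strong sets per method and sex; the consensus is the
intersection across methods per sex. Report percentages are rounded
half-up to one decimal from integer counts (so 7/82 → 8.5, 7/171 → 4.1,
4/171 → 2.3); nothing is carried over from published rounded values.

### Between-sex comparison

The permutation structure-invariance test compares the sexes' IC-selected
GGMs with the statistic $M = \max_{i<j} |\rho^A_{ij} - \rho^B_{ij}|$, the
standard maximum edge-weight difference; the test itself does not fix a
statistic, so the package states its choice. Group labels are permuted over
pooled rows preserving group sizes, the *entire* fitting procedure
(re-standardization, penalty selection) is re-run per permuted group, and
the p-value uses the add-one correction, so $0 < p \le 1$. The test assumes
comparable group sizes; a ratio above 2 triggers a warning. BN skeletons are
compared by the Hamming distance (size of the symmetric difference of the
strong baseline skeletons).

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| GGM strong cutoff | 0.3 | abs. partial correlation | literature-supported cutoff for metabolite networks |
| BN strong cutoff | 0.85 | bootstrap frequency | conventional default for "strong" arcs |
| BN bootstraps `B` | 1000 | resamples | canonical study value; 100 in the fast profile |
| `gamma` | 0 | EBIC weight | plain BIC is the stated selection criterion |
| grid size / `min_ratio` | 100 / 0.01 | — | unstated in the source analysis; common path defaults |
| `n_perm` | 1000 | permutations | 200 in the fast profile |
| solver `tol` | 1e-4 | successive change | optimality-gap contract of the solver |

## Numerical choices

* The glasso diagonal is unpenalized by default (`penalize_diagonal`
  switches this), matching the common convention for correlation-matrix
  input.
* Entries with $|\Theta_{ij}| < 10^{-10}$ after convergence are structural
  zeros.
* Standardization uses the $n-1$ sample standard deviation and is applied
  *within each analysis stratum* (each sex × timepoint sub-table actually
  fed to a network fit), because networks are fitted per stratum. Pooled
  standardization is available (`standardization: "pooled"` in the pipeline
  config); which of the two the original analysis used is not determinable,
  so both are supported with per-stratum as the default.
* Missing values are a hard error everywhere; the design is complete-case
  and the package never imputes.
* A singular covariance at $\lambda = 0$ is an error advising a positive
  penalty; a penalty value that fails inside a path search is dropped with
  a warning rather than aborting selection.
* Hill-climb moves must improve the score by more than $10^{-10}$;
  candidate moves within $10^{-9}$ of the best are treated as tied and
  resolved lexicographically with operation order add < delete < reverse
  (the tie-break tuple is fixed; the alphabetical operation order is this
  package's stated convention), making `B = 1000` bootstrap runs exactly
  reproducible given a seed.

## The synthetic cohort generator

`make_truth()` plants a sparse precision matrix per timepoint: `n_stable`
edges shared by both timepoints and `n_unstable` additional edges specific
to *each* timepoint, all targeting a planted partial correlation of 0.5
(node-disjoint placement is preferred so the target is hit exactly; the
invariant $|\rho| \ge 0.4$ for every planted edge is verified by direct
computation). Both sexes share one truth, which makes the union of per-sex
consensus sets the natural recovery target and also means the between-sex
invariance test acts as a null check. `simulate_cohort()` draws
multivariate-normal metabolite vectors from the inverse precision,
independently per timepoint (no subject-level carryover — the
reproducibility logic operates on networks, not on paired subjects), and
appends covariates with the published correlation structure (birth
weight–length r ≈ 0.7, energy–protein r ≈ 0.8) independent of the
metabolites. In `"realistic"` mode the Gaussian margins are mapped through
log-normal marginals whose medians and quartiles mimic published 24-h urine
concentration scales (a monotone map, so rank correlations — and hence the
standardized analysis — are essentially unchanged; `"gaussian"` mode is the
default for tests for exactly that reason).

What the generator does *not* emulate: measurement error of the
quantification platform, urine dilution/creatinine effects, covariate
effects on metabolites, subject-level temporal correlation, or non-Gaussian
dependence beyond the marginal transform. Passing recovery tests therefore
demonstrates correctness of the inference machinery under the planted
model, not performance guarantees on real cohort data.

## Problem sizes used in the validation studies

The bundled simulation studies use sizes chosen to make the suite routinely
runnable while keeping the statistical properties interpretable: planted
truths on 6 metabolite nodes; recovery experiments with 150 subjects per
sex, the fast profile (B = 100, 200 permutations, 30-point grid) and 20
seeds; null-calibration studies with 100 replicates of two 80-subject
groups and 200 permutations; exhaustive DAG enumeration on 3 and 4 nodes
(25 and 543 DAGs). The canonical profile (B = 1000, 1000 permutations,
100-point grid) is the default for real analyses.

## Known limitations

* Hill climbing is a local search. On data from dense, collider-rich
  truths, single-move greedy search has *genuine* local optima (the
  global optimum can sit across a score-neutral reversal plateau), so the
  exhaustive-enumeration equivalence checks use tree-structured truths —
  the regime where greedy is expected to reach the optimum — while a
  separate test verifies, for arbitrary dense truths, that the returned
  DAG admits no improving single-arc change. On larger problems the score
  optimum is not guaranteed either way.
* The percentile bootstrap behind the connection-difference test is
  slightly anticonservative at these sample sizes (empirically ~7–8% false
  "different" calls at nominal 5% in the bundled calibration test).
* The invariance test's add-one p-values are discrete and mildly
  conservative at small `n_perm`.
* BN strengths from B resamples are multiples of 1/B; with the fast
  profile's B = 100 the 0.85 cutoff is coarser than with B = 1000.
* With 24 nodes (19 metabolites + 5 covariates) and ~64 subjects per
  stratum, n/p is below 3; the package warns when n ≤ p but proceeds, as
  regularization (GGM) and bootstrap aggregation (BN) are the intended
  mitigations.
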