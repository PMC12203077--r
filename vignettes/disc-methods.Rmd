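---
title: "Distributional feature testing for multi-individual single-cell data: models and methods"
author: "DiSC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional feature testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiSC)
```

## The problem

Modern single-cell experiments measure expression in hundreds of cells from
each of many individuals.  Differential expression (DE) between groups of
*individuals* — cases versus controls, disease severity grades, a continuous
phenotype — must respect that cells within an individual are correlated:
treating cells as independent replicates inflates false positives, while
pseudo-bulk aggregation (summing counts per individual) discards everything
about the within-individual expression distribution except its mean.  A gene
whose expression becomes more *variable* across cells in cases, with an
unchanged mean, is invisible to pseudo-bulk methods.

This package tests association between individual-level variables and the
full *shape* of each gene's cell-level expression distribution.  It applies
equally to scRNA-seq counts and other single-cell modalities such as CyTOF;
cells are assumed to be pre-assigned to the subpopulation under analysis.

## The testing procedure

For gene $i$, individual $j$ with $C_j$ cells, let $x'_{i,j,c}$ be the
total-sum-scaled expression (each cell's counts divided by that cell's
total, so zeros are preserved and depth differences removed).  Three
features summarise the within-individual distribution:

* `zero_prop` — the fraction of zero cells,
* `nonzero_mean` — the mean of the non-zero values,
* `nonzero_sd` — the sample standard deviation ($n-1$ denominator) of the
  non-zero values.

The mean/SD split against the zero fraction is the natural decomposition for
zero-inflated counts; additional features (e.g. higher moments) can be
added with `registerFeature()` and enter the test automatically.

Each feature $w_{i,j,k}$ is transformed to a scale where a linear model is
reasonable: a logit for the zero proportion, capped at $\pm 7$
($w = 0, 1$ map exactly to $\mp 7$, so no infinities arise and extreme
proportions cannot dominate), and a power transform $w^{\rho}$ with
$\rho = 0.5$ for the non-zero mean and SD (a square root stabilises the
right skew of these quantities while keeping 0 a fixed point).  For the
transformed feature vector $U_{i,k} \in \mathbb{R}^N$ the model is

$$ U_{i,k} = Y \alpha + Z \beta + \varepsilon, $$

with $Y$ the $N \times p$ variables of interest and $Z$ the $N \times q$
covariates, and the association strength is the classical nested-model F
statistic written with projection matrices:

$$ F_{k,i} = \frac{U_{i,k}^{\top} (H_{YZ} - H_Z) U_{i,k} / p}
                  {U_{i,k}^{\top} (I - H_{YZ}) U_{i,k} / df}. $$

An intercept is always included in the reduced design.  Degrees of freedom
are rank-based, $df = N - \mathrm{rank}([1, Z, Y])$, which equals the
conventional $N - p - q - 1$ for full-rank designs and stays correct for
rank-deficient ones (projections use a rank-revealing SVD).

The per-feature statistics are combined into an omnibus statistic
$F_{O,i} = \max_k F_{k,i}$ — evidence on *any* distributional axis counts.
Its null distribution is not an F distribution, so inference is by
permutation.

### Permutation and pooled FDR

One permutation plan (B row permutations of the response, default
$B = 999$; $B = 99$ is adequate for study-scale work) is shared by all
genes and features.  This sharing is essential twice over: the pooled FDR
below sums permuted statistics across genes, which requires a common plan,
and the $N \times N$ projection matrices can be computed once per
permutation instead of once per gene — the computational reason the method
scales to thousands of genes.

Without covariates the rows of $Y$ are permuted directly (`plain`).  With
covariates, permuting $Y$ would break the $Y$–$Z$ association under the
null; instead a Smith-type residual scheme is used: $Y$ is residualized
column-wise on $[1, Z]$, the residual rows are permuted, and the permuted
residuals serve as the response of interest while $Z$ stays in both
projections.  With empty $Z$ this reduces to permuting centered $Y$, which
spans the same space as permuted $Y$, so both schemes give identical F
statistics there.

P-values use the plain counting formula
$p_i = \sum_b I(F^b_{O,i} \ge F_{O,i}) / (B+1)$, implemented exactly as
written; it can return 0, and the conventional $(1 + \cdot)/(B+1)$ variant
is available via `pvalueAddOne`.

The FDR-controlling q-value pools all $M \times B$ permuted omnibus
statistics into one empirical null.  With genes sorted by decreasing
observed statistic (ties broken stably by input order),

$$ \tilde q_{(i)} = \frac{\max\left(\#\{(l,b) : F^b_{O,l} \ge F_{O,(i)}\},\ 0.5\right)}{i\,B},
   \qquad q_{(i)} = \min_{j \ge i} \tilde q_{(j)}, $$

the 0.5 pseudo-count guarding the empty-count case.  The numerator divided
by $B$ estimates the expected number of null genes reaching threshold
$F_{O,(i)}$; divided by the $i$ discoveries it is an FDR estimate in the
spirit of pooled-permutation procedures.  The cumulative minimum enforces
monotonicity along the ranking, so thresholding $q$ always selects a
top slice of the omnibus ordering.  Reported q-values are capped at 1; the
uncapped values are kept in the result metadata.

### Numerical corner cases

* Constant transformed features (e.g. an all-zero gene in every individual)
  make both quadratic forms vanish; the statistic is defined as 0 — no
  evidence — rather than NaN, so the omnibus max stays well-defined.
* A vanishing residual form with non-vanishing numerator yields a $+\infty$
  sentinel, which sorts above all finite statistics in the p/q machinery.
* Vanishing is judged against a per-gene tolerance of
  $10^{-10} \sum_j u_j^2$.
* Individuals with no non-zero cells get features $(1, 0, 0)$; a single
  non-zero cell gets SD 0 (the sample SD is undefined at $n = 1$).  Both
  are documented policies, overridable by registering replacement features.
* The sample ($n-1$) SD is used; with unequal $C_j$ this is a genuine
  choice (the $\sqrt{C_j/(C_j-1)}$ factor does not cancel in the F
  statistic) and the sample version is the less biased summary.
* Sparsity filtering removes a gene only when its zero fraction *strictly*
  exceeds the threshold (default 0.8, i.e. "expressed in under 20% of
  cells"), so a gene at exactly 80% zeros is kept.
* Cells with zero total count cannot be normalized and are dropped with a
  warning; an individual losing all its cells that way is an error.

## The simulator

The generator emulates a multi-individual scRNA-seq experiment through a
three-level hierarchy, with all parameters on transformed scales (log mean,
log dispersion, logit zero probability, log between-cell SD):

1. **Population:** each gene gets $(\mu_i, \phi_i, \pi_i, \sigma_i)$.
2. **Individuals:** $(\mu_{ij}, \phi_{ij}, \pi_{ij}, \sigma_{ij}) \sim
   \mathrm{MVN}((\mu_i, \phi_i, \pi_i, \sigma_i), \Sigma)$, and a
   standard-normal individual covariate $z_j$ shifts the log-mean by
   $\beta z_j$ (default $\beta = 0.1$), emulating a technical covariate
   such as sample quality.
3. **Cells:** per-cell log-means $\sim N(\mu_{ij}, \sigma_{ij}^2)$
   (optionally plus a per-cell log size factor); dispersion and zero
   probability are inherited from the individual; counts are emitted from
   the zero-inflated negative binomial with mean $m = e^{\cdot}$, size
   $\phi = e^{\phi_{ij}}$ (variance $m + m^2/\phi$ — "size"
   parameterisation, stated explicitly because "dispersion" is overloaded)
   and zero-inflation $\mathrm{logit}^{-1}(\pi_{ij})$.

DE signals are injected into the individual-level parameters of case
individuals only: three disjoint random gene sets (default 5% of genes
each) receive a mean shift $\pm\log f$, a multiplicative $f^{\pm 1}$ on the
between-cell SD, or both with a shared sign; direction is equally likely
up or down.  $f = 1$ is an exact no-op — the global null — and every gene
is then labelled `none`.

Counts are drawn through per-gene RNG substreams with control individuals
laid out before cases, so two datasets generated from one seed that differ
only in $f$ differ exactly at the DE-gene × case-individual entries.  This
makes signal injection auditable at the count level.

### Default parameters and why

The reference estimates behind such simulations come from fitting real
cortical scRNA-seq data; those fits are not portable, so the defaults here
are documented distributions chosen once to represent a realistic UMI
panel, and everything is overridable (including via a parameter TSV):

| parameter | default | rationale |
|---|---|---|
| $\mu_i$ | $N(0.5, 1^2)$ | per-cell means centred near 1.6 counts, spanning sparse to abundant genes |
| $\phi_i$ | $N(0, 0.5^2)$ (log) | dispersion around 1, typical UMI overdispersion |
| $\pi_i$ | $N(-2, 1^2)$ (logit) | zero inflation around 12% on top of NB zeros |
| $\sigma_i$ | $N(\log 0.7, 0.25^2)$ (log) | between-cell SD of log-means ≈ 0.7: biological cell-to-cell variability is a real axis, large enough that dispersion changes are biologically meaningful against counting noise |
| $\Sigma$ | diag(0.0225, 0.01, 0.04, 0.0225) | between-individual SDs ≈ 0.15/0.10/0.20/0.15: ~15% inter-individual CV on means, so fold changes 1.1–1.5 traverse low to high power |
| $\beta$ | 0.1 | a mild technical covariate effect on the log-mean |

These choices give marginal gene sparsity mostly between 0.2 and 0.8 —
matching data analysed after the customary 80% sparsity filter — and were
fixed at design time from pilot draws of the generator itself.

What the generator does **not** emulate: batch effects, doublets, varying
cell numbers across individuals within one dataset, gene–gene correlation
(genes are conditionally independent given the hierarchy), and
cell-clustering uncertainty.  Passing calibration and power checks on these
simulations therefore demonstrates correctness of the statistical
machinery under the stated hierarchy, not robustness to every artefact of
real data.

## The study harness

`runStudy()` loops scenario → per-run derived seed → generate → 80%
sparsity filter (mirroring real preprocessing; filtered genes count as
negative calls) → test → score, and aggregates means and standard errors.
Metrics follow the usual definitions: type I error is the fraction of true
null genes with raw $p < 0.05$; FDP $= FP/\max(TP+FP, 1)$ at the 10%
q-value target, whose average over runs is the empirical FDR; TPR
$= TP/(TP+FN)$, overall and per signal type.  Under a global null, mean
FDP coincides exactly with the fraction of runs having any positive —
both are computed and asserted equal in the tests.

The shipped studies run at desk scale: 1000 genes, 24 individuals, 375
cells per individual, $B = 99$, 100 null runs and 20 runs per power
scenario (the `global-null-paper-scale` preset provides the 8000-gene
variant).  The package's own test suite and `scripts/acceptance.R`
recompute all reported operating characteristics at exactly these sizes;
the vignette intentionally quotes none that they do not compute.

## Known limitations

* Power for variance-type signals depends on the between-cell biological
  variance being resolvable against counting noise; for very low-expressed
  genes the `nonzero_sd` feature is dominated by NB noise.
* The permutation p-value floor is $1/(B+1)$ only with `pvalueAddOne`;
  as printed the formula can return 0.
* The Smith residual-permutation scheme is one established variant of
  covariate-adjusted permutation; with strongly non-exchangeable errors
  under the reduced model, permutation schemes of this family are
  approximate.
* Ordinal variables of interest are treated as numeric scores (0–3 style
  coding); users wanting factor contrasts should expand them into columns.
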