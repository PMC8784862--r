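---
title: "Distribution-based differential expression across individuals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-based differential expression across individuals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scDistDE)
```

# The inferential target

With scRNA-seq data from $n$ individuals (say $n_1$ cases and $n_2$
controls), `scDistDE` asks, gene by gene, whether the *distribution* of
that gene's expression across an individual's cells is associated with a
phenotype, treating the individual — not the cell — as the sampling unit.
The package assumes cells have already been assigned to a cell type; one
analysis covers one cell type.

The pipeline per gene is: estimate one expression distribution per
individual; compute all pairwise distances between these $n$
distributions; test the association between the resulting distance matrix
and the phenotype with a covariate-adjusted pseudo-F statistic and a
permutation null.

# Estimating per-individual distributions

## Parametric (default)

Counts $y$ of one individual's cells are modelled as negative binomial
with a log-linear mean in the cell-level covariates (at minimum `log_rd`,
the log of the cell's total count): read depth varies by orders of
magnitude across cells and would otherwise dominate the estimated
distribution. The individual's distribution is the *conditional* NB at a
common reference covariate value, by default the per-covariate median over
all cells of all individuals, so that all $n$ distributions are comparable
at the same depth. The zero-inflated variant adds a logit-linear zero
component,
$$f(y) = \pi\,I(y = 0) + (1 - \pi)\,f_{NB}(y;\, \mu, \theta),
\qquad \mathrm{Var}_{NB} = \mu + \mu^2/\theta .$$
For UMI data the plain NB is usually sufficient, which is why `fit = "nb"`
is the default and the ZINB is offered for non-UMI protocols.

Fitting uses `MASS::glm.nb`; the ZINB likelihood (same covariates in both
components by default, intercept-only zero model as an option, since the
appropriate zero covariate set is genuinely open) is maximised by BFGS
from an NB warm start. A *fallback ladder* keeps estimates in-range:
ZINB collapses to NB when the conditional zero estimate is negligible
($\hat\pi < 10^{-4}$) or the optimisation fails; NB collapses to Poisson
when $\hat\theta > 10^4$ (no evidence of overdispersion) or the theta
iteration diverges; all-zero or zero-variance input fails outright. A gene
is testable only if *every* individual has a non-failed distribution —
dropping individuals per gene would change $n$ across genes and silently
alter the permutation null — and each individual needs at least
`min_cells` cells (default 10, below which a conditional fit is too noisy
to be meaningful).

## Non-parametric

The `kde`/`empirical` paths regress $\log(1+y)$ on the covariates by
ordinary least squares and carry forward, per cell, the fitted value at
the reference covariates plus the residual. The `+1` pseudocount is the
conventional choice that keeps zeros finite. Kernel density estimates use
a Gaussian kernel with Silverman's rule-of-thumb bandwidth on a shared
512-point grid spanning all individuals' values plus three bandwidths of
padding, renormalised to integrate to one by the trapezoid rule. These
paths are provided for completeness but are unreliable when most counts
are 0–5 — a linear model on nearly-constant log counts is ill-conditioned
— which is the practical reason the parametric path is the default.

## Denoiser output

External denoisers emit one distribution per gene and cell (ZINB
parameters, or a Poisson mean). Two routes turn these into individual
distributions: *aggregate* (default) averages the cell-level pmfs — the
individual's law is the equal-weight mixture over its cells — and *sample*
draws `m_sample = 5` counts from each cell's distribution and refits the
NB regression, which is slower but keeps covariate adjustment available.

# Distances

Two metrics are implemented. Wasserstein-1 (default), computed exactly for
discrete count distributions as the sum of absolute CDF differences over
unit bins; and Jensen-Shannon divergence in natural-log units, so its
range is $[0, \ln 2]$. The log base is a pure rescaling of the distance
matrix, and because p-values are permutation ranks of a trace ratio they
are invariant to it. Parametric fits are discretised onto a common support
$0..K$, with $K$ the smallest integer leaving tail mass below $10^{-6}$
and the remaining tail folded into the top bin so every density sums to
one exactly. Distances below $10^{-14}$ are clamped to zero to avoid
negative round-off.

# The test

With distance matrix $D$, set $A = -\tfrac12 D^{\circ 2}$ and Gower-center
$G = (I - \tfrac1n \mathbf{1}\mathbf{1}')\,A\,(I - \tfrac1n
\mathbf{1}\mathbf{1}')$. $G$ may have negative eigenvalues when $D$ is not
Euclidean; these are truncated to zero. Truncation cannot break the
centering: $\mathbf{1}$ spans the null space of $G$, so every eigenvector
with nonzero eigenvalue is orthogonal to it and row sums remain zero.

With $Z$ the design (intercept, phenotype $X$, individual-level
covariates) and $H = Z(Z'Z)^{-1}Z'$,
$$F = \frac{\mathrm{tr}(H G H)}{\mathrm{tr}[(I - H)\,G\,(I - H)]}.$$
Both traces are computed from a thin QR of $Z$
($\mathrm{tr}(HGH) = \mathrm{tr}(Q'GQ)$, and the residual trace as
$\mathrm{tr}(G)$ minus it, valid because $H$ is idempotent). Including the
covariates in $H$ — rather than only $X$ — removes their effect from both
traces and increases power when covariates matter.

The null distribution is obtained by permuting the $X$ column only,
rebuilding $Z$, and recomputing $F$ against the *same* $G$; permuting $X$
with $G$ fixed is algebraically identical to permuting $G$'s rows and
columns with $X$ fixed (tested to $10^{-12}$). The p-value is the add-one
estimator $(1 + \#\{F_b \ge F_{\mathrm{obs}}\})/(1 + B)$, with ties
counting as exceedances — the conservative convention, chosen because it
guarantees $P(p \le \alpha) \le \alpha$ under exchangeability; other
implementations may break ties differently. For binary $X$ with
$\binom{n}{n_1} \le B$ the null is enumerated exhaustively and the p-value
is the exact proportion of assignments (observed included) at or above
$F_{\mathrm{obs}}$. A `resample` mode redraws $X$ given the covariates
(logistic fit for binary $X$), which preserves $X$–covariate association
but is unstable at small $n$, so plain permutation is the default. With
`early_stop = TRUE` (default) a gene stops after 100 permutations once its
running p-value exceeds 0.5: clearly-null genes get cheap, coarse
p-values, while small p-values always use the full budget (999 by default;
9999 is recommended for final analyses). Each gene's permutation stream is
seeded from (global seed, gene index), so results are independent of
worker count and reproducible gene by gene.

# The simulator

The generator mirrors the study conditions under which the method is
meant to operate. Each gene has a 4-dimensional latent parameter law —
log NB mean, log overdispersion, logit zero proportion, log of the
cell-level log-mean sd — and individuals are multivariate-normal draws
from it. Cells of individual $i$ get a lognormal mean
$\exp\!\big(N(\log\mu_i - \sigma_i^2/2,\ \sigma_i)\big)$ (the correction
keeps the average cell mean at $\mu_i$) and a ZINB count around it.

`default_param_model()` provides a self-contained bank of plausible gene
models: latent means with log mean in $[-2, 2]$, log overdispersion in
$[-1, 2]$, cell-level log-mean sd in $[0.1, 0.6]$, and a zero-inflation
logit of $U(-3, 0)$ *minus* the log mean, encoding the empirical fact that
dropout anticorrelates with abundance; this coupling also guarantees the
bank spans per-gene zero fractions from below 5% to above 80%.
Between-individual latent sds are modest (0.05–0.5 by channel) with weak
random cross-correlations built as $\mathrm{diag}(s)\,R\,\mathrm{diag}(s)$
from a random correlation matrix, so positive semidefiniteness holds by
construction. These choices were fixed once, as a stand-in for parameters
one would estimate from a reference dataset.

Signals: *meanDE* multiplies case-group $\mu_i$ by the fold (1.2 by
default), with a per-gene random direction. *varDE* (1.5-fold by default)
is the single largest interpretive choice in the package: the fold is
applied to the implied cell-level count variance while holding the mean
exactly fixed, by rescaling the $\sigma$ channel. Writing
$W$ for the NB count with lognormal mean ($\mathrm{E}[W] = \mu$,
$\mathrm{Var}(W) = \mu - \mu^2 + (1 + 1/\theta)\mu^2 e^{\sigma^2}$) and
$Y = \mathrm{Bern}(1-\pi) \cdot W$, requiring
$\mathrm{Var}(Y)' = r_v \mathrm{Var}(Y)$ at fixed mean gives
$\mathrm{Var}(W)' = r_v \mathrm{Var}(W) + (r_v - 1)\pi\mu^2$, which always
has a real $\sigma'$ solution for $r_v \ge 1$. This channel is exactly the
one a pseudo-bulk mean comparison cannot see, which is what makes the
varDE power comparison meaningful. Read depth is the realized column sum
of the simulated matrix — the test conditions on observed depth, so no
separate depth model is imposed. Whether a real study's variance signal
acts on the latent mean spread or elsewhere is unknowable from the
simulation alone; passing tests show correct behaviour *under this
generator*, not under every real-data departure from it (no batch
effects, doublets, ambient RNA, or multi-cell-type mixtures are
simulated).

# Baseline and summaries

The pseudo-bulk baseline sums each individual's counts and runs, per gene,
an NB regression with a log total-depth offset and a Wald test on the
phenotype coefficient. It is deliberately a plain mean-model — no
shrinkage machinery — because its role here is qualitative: strong power
on mean shifts, near-nominal rejection on variance-only signals.

Multiplicity uses Storey q-values with $\lambda$ fixed at $0.5$:
$\hat\pi_0 = \mathrm{mean}(p > 0.5)/0.5$ clamped to $(0, 1]$, and
$q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}_j$; with
$\hat\pi_0 = 1$ this is exactly Benjamini–Hochberg (tested against
`p.adjust`). The global DE-proportion estimate is
$1 - 2\,\hat p_0(0.5)$, clamped to $[0, 1]$ because the raw formula can go
negative. A per-individual moment summary — mean and the pseudo-dispersion
$\hat\theta = \hat\mu^2 / (\hat\sigma^2 - \hat\mu)$, the exact inverse of
the NB mean-variance relation, with an infinity sentinel when
$\hat\sigma^2 \le \hat\mu$ — feeds an exploratory, non-canonical
`moment_association_test()` that reuses the permutation machinery on
absolute differences of a scalar, to ask whether a signal lives in the
mean or the dispersion.

# Numerical and design notes

* Gene filter: a gene is analysed if expressed (nonzero) in at least 20%
  of cells; the threshold is inclusive.
* Cells with zero total count are excluded up front (their log read depth
  is undefined), with a warning.
* Counts must be integers; floats within $10^{-8}$ of an integer are
  accepted for MatrixMarket "real"-dialect files, anything else errors.
  Duplicate gene or cell ids are errors, never silently deduplicated.
* Matrix orientation is genes × cells; a transposed file must be declared
  (`transpose = TRUE` / `--transpose`), not auto-detected.
* Discrete densities must sum to 1 within $10^{-10}$; discretisation folds
  tail mass into the top bin to keep this exact.
* An asymptotic (kernel-regression) p-value path for large $n$ is *not*
  implemented; only permutation p-values are produced.
* Severe group imbalance (a group below 3) triggers a warning: few
  distinct permutations exist and p-values are coarse.

# Problem sizes used in the shipped checks

The package's statistical checks run at desk scale, chosen to keep the
whole suite in minutes while leaving enough genes for stable rates: null
calibration on 300 equivalently expressed genes (10 vs 10 individuals, 90
cells each, up to 499 permutations); variance-signal power on 100 genes at
1.5-fold variance and mean-signal power at folds 1.0/1.2/1.5 on 100 genes
each (10 vs 10, 360 cells per individual); parameter-recovery at 2000
(NB) and 5000 (ZINB) cells. Because all genes of one simulated dataset
share the same drawn individuals, per-dataset error rates are more
variable than independent-gene binomial noise would suggest; across
independent replicates the type-I error averages to the nominal level.

# Limitations

Cells must be pre-clustered into types; comparing *different* cell types
across individuals is out of scope. Only one variable of interest is
tested at a time (binary or continuous); multi-level factors beyond two
groups and repeated-measures designs are not supported. Non-parametric
estimators are unreliable on very sparse genes. The package consumes
denoiser *output* but does not run denoisers, and the baseline is not a
substitute for a full bulk DE analysis — it exists for the power
comparison.
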