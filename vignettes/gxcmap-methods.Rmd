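---
title: "Mapping genotype-by-context interactions in single cells: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genotype-by-context interactions in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An eQTL study with single-cell RNA-seq readout measures, for each gene, one
expression value per cell, with hundreds or thousands of cells per donor.
The allelic effect of a regulatory variant need not be constant across cells:
it can strengthen, vanish, or flip sign along a differentiation trajectory,
across cell types, or with cell-intrinsic states such as the cell cycle.
`gxcmap` models these genotype-by-context (GxC) interactions directly against
*continuous* cellular contexts, avoiding the loss of power and resolution
that comes from discretizing cells into clusters before testing.

## The model

For one gene and one variant, with $y$ the (quantile-normalized) expression
across $N$ cells, $g$ the donor genotype dosage expanded to cells, and $C$ an
$N \times k$ matrix of standardized per-cell contexts (e.g. factor-analysis
factors or principal components computed upstream):

$$
y = g\beta_G \;+\; g \odot \beta_{GxC} \;+\; u \;+\; c \;+\; e
$$

* $\beta_G$ — the persistent (context-independent) allelic effect, a fixed
  effect;
* $\beta_{GxC} \sim \mathcal N(0,\, \sigma^2_{GxC}\,\Sigma)$ — a per-cell
  random allelic effect with prior covariance the context covariance
  $\Sigma = CC^\top$: cells in similar states have similar allelic effects;
* $c \sim \mathcal N(0,\, \sigma^2_{C}\,\Sigma)$ — additive context effects
  on expression;
* $u \sim \mathcal N(0,\, \sigma^2_{RC}\, R \odot \Sigma)$ — the
  repeat-structure term: $R$ is the donor relatedness matrix expanded to
  cells (identity kinship by default, i.e. pure repeat structure), and the
  Hadamard product with $\Sigma$ captures donor-specific responses to
  context. Omitting this term — as GxE models designed for one sample per
  individual do — leaves donor-by-context variation on the residual and
  inflates the interaction test, which the calibration experiments in the
  test suite reproduce;
* $e \sim \mathcal N(0, \sigma^2_n I)$ — residual noise.

Discrete contexts enter through one-hot encoding (then standardized like
continuous ones); their unstandardized $\Sigma$ is the block-diagonal
same-group indicator.

## Tests

**Interaction (score test).** The null ($\sigma^2_{GxC} = 0$) model
$y = g\beta_G + u + c + e$ is fitted by REML; the score statistic for the
variance component whose covariance derivative is
$D_g \Sigma D_g = FF^\top$, $F = \mathrm{diag}(g)\,C$, is
$Q = \tfrac12 r^\top K_0^{-1} F F^\top K_0^{-1} r$. Under the null, $Q$ is
distributed as $\sum_i \lambda_i \chi^2_1$ with $\lambda_i$ the eigenvalues
of $\tfrac12 F^\top P_0 F$ — a $k \times k$ problem, never $N \times N$. The
tail probability is computed by numerical inversion of the mixture's
characteristic function (adaptive quadrature, relative tolerance $10^{-12}$,
flagged `davies`), with Liu's three-moment approximation as fallback
(flagged `liu_fallback`) when the quadrature's own error estimate does not
resolve the p-value; p-values are floored at $10^{-30}$.

**Association (LRT).** $\beta_G \ne 0$ is tested by an ML likelihood ratio
between $y = u + c + e$ and $y = g\beta_G + u + c + e$, referred to
$\chi^2_1$. A fast mode holds the genotype-free null's variance components
fixed and refits only the fixed effects by GLS per variant (the classical
fast-LMM shortcut); it is the default inside discovery scans and flagged in
output, with the exact refit used for final reporting.

**Comparators.** `single_env_lrt` (per-context fixed interaction, minimum p
Bonferroni-adjusted by $k$; fixed-background GLS LRT), `multi_env_lrt`
($k$-df joint fixed interaction, by default a genuine ML LRT that refits the
variance components under both models), and
`interaction_test_no_relatedness` (the score test without
$R \odot \Sigma$). All share the null background of the main test. The
multi-context LRT is kept only for benchmarking: its interaction columns lie
inside the span of the donor-by-context random effect (the genotype is
constant within donor), so the alternative refit absorbs random-effect
variance and the $\chi^2_k$ reference fails as $k$ grows; the
`refit = FALSE` variant holds the null covariance fixed, stays calibrated,
and coincides with `single_env_lrt` at $k = 1$.

**Per-cell effects (BLUP).** Under the alternative fit (REML, warm-started
from the null), the posterior mean of the interaction effect is
$\hat\beta_{GxC} = \hat\sigma^2_{GxC}\, \Sigma D_g K^{-1}(y - X\hat\beta)$,
evaluated through the factors as $C\,(C^\top (g \odot K^{-1} r))$. Cells are
then stratified by $|\hat\beta_{GxC}|$ (top/bottom $\lfloor qN \rfloor$,
default $q = 0.3$, ties broken by cell order), sign-flip genes are flagged
when at least 25% of cells have a total effect $\beta_G + \beta_{GxC,i}$ of
opposite sign to $\beta_G$, and pseudo-bulk regressions per stratum confirm
opposite slopes. The sign-flip criterion can alternatively compare the GxC
portion itself (`mode = "gxc"`); the total-vs-persistent comparison is the
default because it is the biologically interpretable statement ("the allele
acts in opposite directions in different cells").

## Low-rank algebra

Every covariance term has an explicit factor: $\Sigma = CC^\top$ (rank $k$),
$D_g\Sigma D_g$ (factor $\mathrm{diag}(g)C$, rank $k$), and
$R \odot \Sigma$ via the Hadamard factorization — if $R = AA^\top$ then
$R \odot \Sigma = WW^\top$ with columns $a_i \odot c_j$, rank at most
$d \times k$ for $d$ donors. Solves and log-determinants go through the
Woodbury identity / matrix determinant lemma on the stacked factor, and all
likelihood evaluations for a fixed dataset reduce to an $r \times r$ problem
on cached cross-products, so the $N$-dependent work happens once. This gives
the advertised $O(N)$ scaling with $N$ the number of cells at fixed
$d \times k$; no cell-side factorization is implemented for the regime where
$d \times k$ exceeds the number of cells. Factors are never expanded to
dense $N \times N$ matrices outside the test suite's oracles.

## Fitting: numerical choices

* Criterion: REML by default (less biased variance components with more
  than one fixed effect); ML for the association LRT. The REML value omits
  the parameter-free $\log|X^\top X|$ constant.
* The overall variance scale is profiled out in closed form, leaving a
  search over log variance *ratios* — a 2-parameter problem under the null,
  3 under the GxC alternative. This profiling plus Nelder-Mead (Brent for
  one ratio) with a BFGS polish replaces a raw quasi-Newton search on three
  log-variances; the optimum is identical and each simulation replicate is
  several-fold cheaper.
* Multi-start (default 3: equal split, noise-dominant,
  structure-dominant); the simulation drivers use a single start for speed,
  which suffices on these well-behaved likelihood surfaces.
* The log parameterization handles the $\sigma^2 \ge 0$ boundary; components
  below $10^{-8}$ are reported as exactly 0. Convergence diagnostics (final
  numeric gradient norm, start count) ride along on the fit object.
* Near-collinear standardized contexts can make inner matrices borderline;
  Cholesky factorizations of kinship use a jitter ladder
  $10^{-10} \ldots 10^{-6}$ before failing.

## Preprocessing conventions

* Quantile normalization is the rank-based inverse-normal transform
  $\Phi^{-1}((\mathrm{rank}_i - 0.5)/N)$; the symmetric $0.5$ offset avoids
  infinities, ties take average ranks. Constant vectors are a hard error.
* Context standardization uses the population SD convention
  (column $[1,3] \mapsto [-1,1]$).
* Pseudocell aggregation **sums** raw counts within externally supplied,
  donor-nested cluster labels (sums preserve the count nature feeding the
  usual normalize–log–quantile chain); clustering itself is out of scope and
  labels are an input.
* Missing donor dosages: default policy drops the affected cells
  consistently across all inputs; mean imputation is available behind a
  flag. Size-factor normalization is accepted as already applied upstream
  (either scran- or scanpy-style); the package does not re-estimate size
  factors.
* The genotype enters the interaction kernel on its dosage scale (it is not
  centered before forming $D_g \Sigma D_g$); whether reference
  implementations center here is undocumented, so the choice is recorded for
  comparison studies.

## The synthetic-data generator

`simulate_dataset()` emulates the semi-synthetic benchmark design: counts
$y \sim \mathrm{Poisson}(\lambda)$ with
$\lambda = \exp(y_{base} + \sum_i (g \odot c_i)\beta_{GxC_i} + g\beta_G)$,
$\beta_{GxC_i} \sim \mathcal N(0, \sigma^2_G\,\rho_{GxC}/k_{active})$ for the
active contexts and
$\beta_G \sim \mathcal N(0, \sigma^2_G (1 - \rho_{GxC}))$. Defaults are the
benchmark's stated conditions: 50 donors × 100 cells, 500 pairs,
$\sigma^2_G = 0.025$, MAF $\sim U(0.05, 0.5)$, dosages standardized across
donors before applying effects so $\sigma^2_G$ is MAF-comparable.

Two deliberate choices:

* **Variance split.** Drawing each of $k$ active contexts with full variance
  $\sigma^2_G \rho_{GxC}$ would make the *total* interaction variance grow
  with $k$, breaking the reading of $\rho_{GxC}$ as "fraction of genetic
  variance explained by GxC"; the generator therefore divides by
  $k_{active}$. The literal per-context convention is available via
  `split_gxc_variance = FALSE`.
* **Synthetic background.** The original benchmark reuses empirical
  expression backbones, which carry real donor and context structure. The
  fully synthetic mode stands in for that with (chosen once, not revisited):
  base mean count 5 ($b_0 = \log 5$, a typical moderately expressed gene),
  shared context effects with total log-scale variance 0.1, and
  donor-specific context loadings with total variance 0.1. The last item is
  what makes the no-relatedness comparator inflate, as it does on the
  semi-empirical data. What the generator does *not* emulate: overdispersion
  beyond Poisson, dropout structure, batch effects, and correlated contexts.
  A green calibration test therefore establishes correctness of the
  inference machinery under the stated generative world, not robustness to
  every property of real droplet data (the Gaussianization step is what the
  model relies on in both cases).

Monomorphic genotype draws are rejected and resampled; $\lambda > 10^8$
aborts with a pointer at effect/base sizes; all randomness flows from a
single integer seed, and the truth record reproduces $\lambda$ exactly.

## Multiple testing and workflow

P-values are Bonferroni-adjusted within gene (min p × number of tests per
gene, capped at 1), then converted to across-gene q-values with Storey's
method ($\pi_0$ from the $\lambda$-grid $0.05, \ldots, 0.95$ with a
df-3 smoothing spline, evaluated at $\lambda = 0.95$). Below 100 genes the
$\pi_0$ estimate is too unstable and the code falls back to
Benjamini–Hochberg with a warning. The two-stage discovery scan runs the
association test over cis windows (100 kb flanking the gene body, BED-style
0-based half-open coordinates, MAF > 5%), forwards each significant gene's
lead variant at a lenient FDR (default 20%), and applies the interaction
test to the forwarded pairs (significance default FDR 5%; the 10% input
eQTL selection threshold used in reanalysis settings is documented but not a
default).

## Known limitations

* Gaussian working model on quantile-normalized counts: no explicit count
  likelihood, so very lowly expressed genes lose power.
* The relatedness component's cost grows with donors × contexts; cohorts of
  thousands of donors would need the cell-side factorization not implemented
  here.
* Context factors are taken as given; uncertainty in their estimation is not
  propagated.
* `multi_env_lrt` is intentionally shipped in its miscalibrated form as a
  benchmarking comparator; it should not be used for discovery.
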