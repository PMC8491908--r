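---
title: "Multi-study fine mapping with a random-effects model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-study fine mapping with a random-effects model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refinemap)
```

This vignette is the package's own account of the model it fits, the
numerical choices behind the implementation, and what the bundled
simulations do and do not demonstrate.

## Model

A locus contains $M$ SNPs measured in $Q$ independent studies.  Study $q$
contributes a vector of signed Z-scores $S_q$ and an LD matrix $\Sigma_q$
(pairwise Pearson correlations of genotypes).  A causal configuration $C$
is a binary vector over the $M$ SNPs, with independent Bernoulli($\gamma$)
prior per SNP.

Conditional on the non-centrality parameters (NCPs) $\Lambda_{Cq}$ of the
causal SNPs, the classical summary-statistic model is
$S_q \mid \Lambda_{Cq} \sim N(\Sigma_q \Lambda_{Cq},\ \Sigma_q)$: LD
propagates causal signal into correlated SNPs, and the same LD matrix is
the noise covariance.  Across studies we assume the causal SNPs are shared
but their effects are heterogeneous: causal SNP $m$ has a mean NCP
$\lambda_m \sim N(0, \sigma^2)$ shared by all studies, and study $q$
realizes $\lambda_{mq} \sim N(\lambda_m, \tau^2)$.  Integrating the NCPs
out analytically (normal conjugacy) gives the marginal likelihood of the
stacked statistics $S = (S_1, \dots, S_Q)$:
$$S \mid C \sim N\!\left(0,\ \Sigma + \Sigma\,\Sigma_C\,\Sigma\right),
\qquad \Sigma = \mathrm{blockdiag}(\Sigma_1,\dots,\Sigma_Q),$$
$$\Sigma_C = (\tau^2 I_Q + \sigma^2 \mathbf{1}\mathbf{1}^\top) \otimes
\mathrm{diag}(C)$$
in study-major layout (study 1's $M$ SNPs first).  This layout is the
single source of truth for every $MQ$-length vector in the package.  With
per-study sample sizes $N_q$, $\sigma^2$ is interpreted per study as
$N_q\,\sigma_g^2$ and the cross-study covariance becomes
$\sqrt{N_{q_1} N_{q_2}}\,\sigma_g^2$; equal sample sizes recover the
Kronecker form above.  Distinct SNPs' causal effects are independent, so
within-block off-diagonals of $\Sigma_C$ are zero.

Posteriors follow Bayes' rule over an enumerated configuration space: all
configurations with $1 \le k \le K$ causal SNPs ($K = 3$ by default).  The
all-zero configuration is excluded by default — the tool is intended for
loci that carry a significant association, and the confidence-set semantics
("contains *all* causal SNPs") presuppose at least one — but
`include_null = TRUE` restores it.  Per-SNP posterior inclusion
probabilities (PIPs) are sums of normalized configuration posteriors, and
the $\rho^*$-confidence set is the smallest SNP set whose *compatible*
configurations (no causal SNP outside the set) carry mass $\ge \rho^*$.

## Parameters

* $\sigma$ (`ncp_scale`, default **5.2**): the standard deviation of a
  causal SNP's mean NCP, on the Z-score scale.  5.2 is the Z-score at the
  conventional genome-wide significance threshold ($p = 5\times10^{-8}$),
  so the model has power exactly for the variants one would call
  significant in the smallest study; it is a power calibration, not an
  estimate of per-SNP heritability.
* $\tau^2$ (`tau_sq`, default **0.52**, i.e. 10% of $\sigma$): between-study
  heterogeneity variance of a causal SNP's NCP.  Zero forces a fixed-effect
  (identical NCP) model.  The package does not fit $\tau^2$ from data;
  overfitting it per locus is easy and harmful.
* $\gamma$ (`gamma`, default **0.01**): prior causal probability per SNP,
  the customary value in this model family.
* $K$ (`max_causal`, default **3**): maximum causal SNPs per configuration.
  The configuration count is $\sum_{k\le K}\binom{M}{k}$, so runtime is the
  main constraint on $K$.
* $\rho^*$ (`rho_star`, default **0.95**): required posterior mass of the
  causal set.

## Likelihood evaluation

Three interchangeable paths are implemented and cross-tested:

* **dense** — literal evaluation of the $MQ$-dimensional normal density;
  the oracle.
* **fast** — factor $\Sigma$ out:
  $|\Sigma + \Sigma\Sigma_C\Sigma| = |\Sigma|\,|I + \Sigma_C\Sigma|$ and
  $S^\top(\Sigma + \Sigma\Sigma_C\Sigma)^{-1}S =
  S^\top (I + \Sigma_C \Sigma)^{-1} \Sigma^{-1} S$ (the factors do not
  commute; the inverse of the *product* keeps this order).  Because
  $\Sigma_C$ has only $KQ$ nonzero rows, the Woodbury identity and
  Sylvester's determinant theorem reduce both terms to $KQ \times KQ$
  systems.  $S^\top\Sigma^{-1}S$ and $\log|\Sigma|$ are computed once per
  locus; $\Sigma_C$ is never materialized at $MQ \times MQ$ in this path.
* **lowrank** (default) — per study, eigendecompose
  $\Sigma_q = W \Omega W^\top$, drop components with eigenvalue below
  `truncation` ($10^{-8}$) times the largest, and transform
  $S'_q = \Omega^{-1/2} W^\top S_q$.  Under the model above the transformed
  statistics satisfy exactly
  $$S' \sim N\!\left(0,\ I + D\,\Sigma_C\,D^\top\right),
  \qquad D = \Omega^{1/2} W^\top \ \text{(block-diagonal across studies)},$$
  which is well-defined for rank-deficient LD (duplicated SNPs, long
  stretches of near-perfect LD) and, at full rank, differs from the dense
  log-likelihood only by the configuration-independent Jacobian constant
  $\tfrac12\log|\Sigma|$ — so posteriors agree across paths, which the
  test suite verifies rather than assumes.  A published variant of this
  transform uses covariance $I + m B \Sigma_C B^\top$ with
  $B = \Omega^{-1/2} W^\top$ and $m = M$; that form is *not* equivalent to
  the dense model (the derivation it descends from uses a different scaling
  convention), and we therefore use the exact transform by default while
  keeping the variant available (`lowrank_variant = "printed"`, with an
  `m_factor` switch) for sensitivity analysis.

All three paths share one inner kernel: with causal index set $J$
(study-replicated), $\Sigma_{cc} = T \otimes I_k$ the causal block of
$\Sigma_C$, $G$ the causal block of a per-study Gram matrix, and
$P = \Sigma_{cc}^{1/2}$, both the determinant and the quadratic-form
correction reduce to the symmetric positive-definite matrix $I + PGP$,
handled by a single Cholesky factorization per configuration.  All
posterior arithmetic is done in log space with log-sum-exp normalization;
probability-space products underflow already for $M$ in the low hundreds.

Numerical details: eigenvector signs follow a deterministic convention
(largest-magnitude component positive), so transformed statistics are
reproducible across LAPACK builds.  PIP ties in the greedy set construction
are broken by input SNP order.  The greedy set is optimal in most cases but
can exceed the exhaustive minimum occasionally; the test suite measures the
agreement rate against exhaustive subset search at $M \le 10$ instead of
assuming it.  The legacy construction that keeps $\Sigma_C$ full rank by
placing a small $\epsilon$ on non-causal diagonal entries is retained for
dense-path cross-checks (`epsilon`), but the default is $\epsilon = 0$
because the low-rank path removes the original motivation for it.

## Synthetic data

`sim_locus()` (direct path) draws what the model family assumes: causal
SNPs chosen uniformly (resampled until all causal pairs are non-negatively
correlated in every study), mean NCPs $|N(5.2, 1)|$ — effects are taken
non-negative so the "positively correlated causal pair" constraint is
meaningful — per-study NCPs $N(\lambda_m \sqrt{N_q/N_{\min}}, \tau^2)$, and
Z-scores $S_q \sim N(\Sigma_q \Lambda_{Cq}, \Sigma_q)$.  The NCP scale was
chosen as the generator's definition because the model's $\sigma$ parameter
lives on that scale; users who want the individual-level route get it from
`sim_locus_genotype()`, which builds Gaussian-copula genotypes at a target
LD and MAF (latent correlations calibrated through tetrachoric inversion so
the *realized* genotype correlation matches the target), simulates
$y = X\beta + e$ with environmental variance
$\mathrm{var}(X\beta)(1/h^2_{tot} - 1)$ so total heritability is
`n_causal` $\times$ `h2`, and computes marginal-regression Z-scores and
in-sample LD.

What the generator emulates: multi-study loci with shared causal SNPs,
distinct per-study LD, sample-size-scaled NCPs, and effect heterogeneity.
What it does not: allele-coding errors, mismatched reference-panel LD,
population-specific causal variants, overlapping samples, and imputation
noise.  Calibration results on these simulations therefore demonstrate
internal consistency of the model and implementation — not robustness to
those real-data failure modes, of which reference-panel LD mismatch is
usually the most consequential.

Default simulation sizes (two studies, $M = 50$, AR(1) LD with $r = 0.9$
and $0.5$, 1–2 causal SNPs, 100 replicates) are the package's desk-scale
standard: large enough for binomial error on a 95% target to be
informative, small enough that the entire suite runs in minutes on one
core.  The calibration harness (`evaluate_calibration()`) reports
sensitivity (fraction of replicates whose returned set covers all causal
SNPs — under a correctly specified model this must be $\ge \rho^*$ up to
Monte-Carlo error), set sizes, and the mean number of descending-PIP SNPs
needed to reach the full truth.

## Known limitations

* Enumeration is exhaustive in $\binom{M}{\le K}$; loci with many hundreds
  of SNPs and $K > 3$ become slow.  Stochastic configuration search is out
  of scope.
* $\tau^2$ is global: all studies are assumed equally heterogeneous.  With
  several cohorts from one population plus one from another, a sensible
  workflow is fixed-effects meta-analysis within population first, then
  multi-study fine mapping across the population-level results.
* The causal set is returned as one set; partitioning it into per-signal
  credible subsets is out of scope.
* Functional priors (per-SNP $\gamma$) are not implemented.
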