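---
title: "Mutual-information region tests for categorical traits: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information region tests for categorical traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micat)
```

## The problem

Sequencing studies routinely test whether the variants in a gene or region
are jointly associated with a phenotype. Most region tests target binary or
quantitative traits; nominal categorical traits — common in psychiatric
genetics, where affection status is often graded into unordered classes —
are usually shoehorned into pairwise dichotomies. `micat` implements a
nonparametric alternative: treat the *region* as the support of a discrete
random variable and ask whether the distribution of minor alleles across
its sites changes with the trait category.

Throughout, the data are a genotype matrix $X$ ($n$ individuals by $m \ge 2$
sites, entries $X_{ij} \in \{0,1,2\}$ counting minor alleles) and a trait
$Y_i \in \{1,\dots,K\}$.

## The statistics

Define a site-valued random variable $S$ by pseudocounted allele totals:

$$P(S=j) = \frac{\sum_i X_{ij} + 1}{\sum_{j'} \left(\sum_i X_{ij'} + 1\right)},
\qquad
P(S=j \mid Y=k) = \frac{\sum_i X_{ij} I(Y_i = k) + 1}{\sum_{j'}\left[\sum_i X_{ij'} I(Y_i=k) + 1\right]}.$$

The added $+1$ per site keeps every probability strictly positive, so
monomorphic columns and empty-ish strata stay well defined; we therefore
*retain* monomorphic sites by default (an optional filter mirrors the
common preprocessing step of removing sites with no sequence variation).

The **MIT** statistic is the trait-weighted Kullback–Leibler divergence
between conditional and unconditional site distributions,

$$\mathrm{MI}(S,Y) = \sum_{k=1}^{K} P(Y=k)\, \mathrm{KL}\!\left(S\mid Y=k,\; S\right)
 = \sum_{k}\sum_{j} P(S=j, Y=k)\,\log\frac{P(S=j, Y=k)}{P(S=j)\,P(Y=k)},$$

with $P(S=j,Y=k) := P(S=j\mid Y=k) P(Y=k)$ and $P(Y=k)$ estimated by the
empirical proportion $n_k/n$ (its MLE; this makes the weighting the sample
average over categories). Because KL divergence is asymmetric, **aMIT**
averages both directions:

$$\mathrm{aMI}(S,Y) = \tfrac12 \sum_{k}\sum_{j}
 \left[P(S=j,Y=k) - P(S=j)P(Y=k)\right]
 \log\frac{P(S=j,Y=k)}{P(S=j)P(Y=k)},$$

in which every summand is nonnegative (the bracket and the log always share
a sign). Two numerical notes:

* **Pseudocount mismatch.** With pseudocounts,
  $\sum_k P(S=j\mid Y=k)P(Y=k) \neq P(S=j)$ in general, so MIT is not
  exactly a textbook mutual information of an empirical joint; the displayed
  formulas are implemented literally, with $P(S=j)$ always taken from the
  unconditional construction.
* **Logarithm base.** Natural log by default. The base rescales both
  statistics by a positive constant and cannot change any permutation
  p-value; a `base` argument exists and the invariance is under test.

Both statistics are invariant to the order of individuals, the order of
sites and the labelling of categories. They are *not* invariant to allele
flips ($x \mapsto 2-x$), which is why the file readers re-orient every site
to the sample minor allele (frequency $\le 0.5$, ties kept as read) and log
what they flipped. They are undefined for $m=1$ (a one-point distribution
carries no between-category signal) and the constructors refuse such
regions.

## Inference

Significance comes from the permutation null: shuffle the trait labels
uniformly ($B$ independent shuffles, genotypes fixed), recompute the
statistic, and estimate

$$p = \frac{1}{B}\sum_{b=1}^{B} I\!\left(T^{(b)} \ge T\right).$$

Division is by $B$, not $B+1$, so $p = 0$ is possible; the print method and
CLI then report `p < 1/B` rather than a bare zero. Ties are counted by the
literal `>=` with no floating-point tolerance — differences at machine
epsilon are noise under either convention. One user seed drives the whole
permutation stream; MIT and aMIT share the same shuffles (both are
functions of the same category-by-site count table), which also makes the
pair comparable replication by replication.

## The parametric comparator

The score test under the baseline-category logit model
$\log\left(\pi_k(X_i)/\pi_K(X_i)\right) = \alpha_k + X_i'\beta_k$
($k < K$, last category baseline) tests $H_0: \beta_1 = \dots = \beta_{K-1} = 0$
with only the null fit, which is intercept-only with
$\hat\pi_k = n_k/n$. We profile the intercepts out at the null —
equivalently, center each genotype column — giving the efficient score
$U_k = X_c'(I(Y=k) - \hat\pi_k)$ and the efficient information
$V \otimes X_c'X_c$ with $V = \mathrm{diag}(\pi) - \pi\pi'$ over non-baseline
categories. The statistic $U'I^{-}U$ is referred to $\chi^2_{m(K-1)}$.
At the null MLE this profiled form coincides with inverting the full
(intercept + slope) information and restricting to the slope block; the
test suite asserts the equivalence numerically against an independently
coded full-parameter implementation rather than assuming it.

Rare-variant designs are often rank deficient (constant or collinear
columns). The efficient information is inverted by an eigenvalue-thresholded
pseudo-inverse (relative tolerance $10^{-10}$ times the largest eigenvalue)
and the retained rank drives the degrees of freedom; constant columns are
reported as carrying no information. The score vector always lies in the
retained eigenspace, so the statistic is well defined. Only when *no* site
varies is the design refused outright.

## The simulator

The generator emulates a standard benchmark design for rare-variant
methods: a registry of ten scenarios mixes rare causal (RC), rare
non-causal (RNC), common causal (CC) and common non-causal (CNC) variants
($m = 24$ or $32$ sites), with per-class MAF ranges (rare 0.005–0.05,
common 0.1–0.5) and class positions arranged uniformly at random.

Haplotypes come from a latent Gaussian vector $Z \sim N(0, \Sigma)$ with
unit marginals, $\mathrm{Corr}(Z_j, Z_{j'}) = \rho^{|j-j'|}$ when sites $j$
and $j'$ are both causal or both non-causal (original position indices) and
$0$ across the two blocks; each block is a principal submatrix of a full
AR(1) matrix, so $\Sigma$ is positive definite for $\rho \in [0,1)$. Site
$j$ carries the minor allele iff $Z_j < \Phi^{-1}(\mathrm{MAF}_j)$ — the
lower-tail convention, fixed and documented because either tail gives the
same marginal and within-block dependence. A genotype is the sum of two
independent haplotypes sharing the same MAFs and $\Sigma$ (no inbreeding,
no cross-haplotype dependence). Traits are drawn from the
baseline-category logit with registered intercepts
(e.g. $\alpha = (-\log 4, -\log 3)$ for $K=3$, giving null category
frequencies $(3,4,12)/19 \approx (0.158, 0.211, 0.632)$) and registered
causal effect vectors stored as exact log ratios; variants of scenario 10
raise the fraction of risk-increasing causal effects to 75% and 100%.

The Monte-Carlo design simulates one population *pool* per experiment
(MAFs and positions drawn once, default 200,000 individuals) and samples
$n$ individuals without replacement per replication. The default pool is
a tenth of the 2,000,000 sometimes used for this design: sampling 1,000
individuals from 200,000 is statistically indistinguishable from sampling
from a pool ten times larger, and the larger value remains one
configuration flag away. A `redraw_pool` flag instead regenerates MAFs and
positions per replication for ablations. Seeding is hierarchical — one
master seed spawns child streams for positions, MAFs, haplotypes, trait and
sampling — so toggling one stage never shifts the others.

What the generator does **not** emulate: coalescent genealogies,
recombination maps, selection, population structure, genotyping error or
missingness. Calibration and power results under this generator therefore
speak to the latent-Gaussian LD model only; on real data the tests carry no
model assumptions, but their power profile may differ.

## The evaluation harness

`run_experiment()` estimates rejection rates: per replication, sample from
the pool, compute each requested test's p-value (permutation for MIT/aMIT,
$\chi^2$ tail for Score — downstream both are thresholded identically),
reject when $p \le \alpha$ (the `<=` is deliberate), and report the rate
with its binomial standard error $\sqrt{r(1-r)/R}$. Replication seeds
derive deterministically from the master seed, so results do not depend on
execution order. Defaults are desk scale: $R = 200$ replications, $B = 500$
permutations, $n = 1000$, pool 200,000 — Monte-Carlo standard errors of
about 0.015 at $\alpha = 0.05$ and about 0.035 at power 0.5, adequate for
three-standard-error comparisons; reference scale ($R = 1000$, $B = 1000$,
pool 2,000,000) is reachable through the same configuration object. The
test suite exercises null calibration at $R = 500$, $B = 500$ on a reduced
sample size, and the acceptance checks run the full desk-scale cells.

## Degenerate inputs and tie-breaks, collected

* $m = 1$ regions: refused ("region too small").
* $K = 1$ traits: the bare statistics return exactly 0; ingestion and the
  region-test entry points require $K \ge 2$ with every category observed.
* Empty trait stratum: refused at validation ("empty stratum").
* All-zero genotype columns: retained, handled by pseudocounts; the score
  test drops their information and reduces its degrees of freedom.
* Permutation ties: counted by `>=`, no tolerance; $p = 0$ reported as
  `p < 1/B`; $p$-value estimator divides by $B$.
* Allele orientation at exactly 0.5 frequency: kept as read.
* Missing genotypes at ingestion: imputed to 0 copies with a logged count
  (conservative for rare variants), or individuals dropped via a flag.
  Missing phenotype labels: individuals dropped with a warning.
* $\alpha = 1$ in the harness: admitted as a degenerate threshold (every
  replication rejects), useful only as a counting identity.

## Known limitations

* Permutation inference is exchangeable-null only: no covariate adjustment,
  no stratified shuffling (the uniform shuffle matches the unadjusted
  tests).
* The MIT/aMIT power degrades when all variants are causal with identical
  effects — the $K+1$ site distributions then barely differ — and the tests
  cannot see effects that cancel in the site totals.
* The score test's $\chi^2$ is asymptotic; with many rare variants and
  small $n$ its calibration relies on the pseudo-inverse rank reduction.
* VCF support is deliberately minimal: biallelic, diploid, GT-only.
  Multiallelic records must be split upstream.
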