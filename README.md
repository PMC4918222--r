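# micat — mutual-information region tests for categorical traits

`micat` tests whether the genetic variants in a gene or region are jointly
associated with a **nominal categorical trait** (K unordered levels, e.g. a
three-way affection scale in psychiatric genetics). Most region tests
target binary or quantitative phenotypes; `micat` provides a nonparametric
route that handles rare and common variants together and makes no modelling
assumption about how genotype drives category membership.

## The statistics

For genotypes `X` (n individuals × m ≥ 2 sites, minor-allele counts 0/1/2)
and trait `Y ∈ {1..K}`, define a site-valued random variable `S` with
pseudocounted probabilities

    P(S = j)       ∝ Σ_i X_ij + 1
    P(S = j | Y=k) ∝ Σ_i X_ij I(Y_i = k) + 1

The **MIT** statistic is the trait-weighted Kullback–Leibler divergence
between conditional and unconditional site distributions,

    MI(S, Y) = Σ_k P(Y=k) · KL(S|Y=k, S),

which is zero under independence and grows with the between-category
difference in where the region's minor alleles sit. Because KL divergence
is asymmetric, the adjusted statistic **aMIT** averages the two directions:

    aMI(S, Y) = ½ Σ_k Σ_j [P(S=j,Y=k) − P(S=j)P(Y=k)] · log{ P(S=j,Y=k) / (P(S=j)P(Y=k)) }.

Significance comes from a permutation null (`p = Σ_b I(T⁽ᵇ⁾ ≥ T)/B` over B
trait shuffles). The baseline-category-logit **score test**
(χ² with m(K−1) degrees of freedom, intercept-only null fit) is included as
the parametric comparator. A latent-Gaussian simulator with AR(1) linkage
disequilibrium and a registry of ten benchmark scenarios, plus a
Monte-Carlo harness for type-I error and power, complete the package. See
`vignettes/mutual-information-region-tests.Rmd` for the full model account.

## Worked example

Simulate one benchmark dataset — scenario 10 (8 rare causal + 24 rare
non-causal sites), strong LD (ρ = 0.9), all causal effects risk-increasing,
K = 3 categories, n = 1000 — and test the region:

```r
library(micat)
cfg <- scenario(10, K = 3, rho = 0.9, effect_profile = "100",
                n_sample = 1000, pool_size = 50000)
dat <- generate_dataset(cfg, seed = 2026)

res <- mi_region_test(dat$geno, dat$trait, tests = c("MIT", "aMIT"),
                      B = 1000, seed = 1)
res$MIT
#> MIT region test (permutation, B = 1000)
#>   statistic = 0.0396108
#>   p-value   < 0.001  (no permuted statistic reached the observed one)
res$aMIT
#> aMIT region test (permutation, B = 1000)
#>   statistic = 0.0414634
#>   p-value   < 0.001  (no permuted statistic reached the observed one)
score_statistic(dat$geno, dat$trait)
#> Baseline-category-logit score test
#>   statistic = 131.071 on 64 df (chi-square), p-value = 1.593e-06
```

Both mutual-information statistics exceed every one of the 1000 permuted
values (reported as `p < 1/B` rather than a bare zero), and the parametric
comparator agrees that the region is associated — here the association is
real by construction, planted at the 8 causal sites.

The same analyses run from the shell on files (genotype TSV or
biallelic GT-only VCF plus a two-column phenotype TSV):

```sh
inst/scripts/micat test --geno region.vcf --pheno pheno.tsv \
    --tests MIT,aMIT,Score -B 1000 --seed 7
inst/scripts/micat simulate --scenario 10 -K 3 --rho 0.9 -n 1000 --seed 1 --out-prefix sim
inst/scripts/micat power --scenario 10 --rho 0,0.5,0.9 --effect-profile 100 --out pow
```

Sites are re-oriented so the counted allele is the sample minor allele
(logged), since the statistics are not invariant to allele flips.

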