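test_that("scenario registry reproduces the benchmark settings verbatim", {
  s10 <- scenario(10, K = 3)
  expect_equal(unname(s10$counts), c(8, 24, 0, 0))
  expect_equal(s10$m, 32)
  expect_equal(s10$maf_ranges$RC, c(0.005, 0.01))
  expect_equal(s10$maf_ranges$RNC, c(0.01, 0.05))
  expect_null(s10$maf_ranges$CC)
  expect_equal(s10$alphas, c(-log(4), -log(3)))
  expect_equal(s10$beta_rc[1, ],
               c(log(5/2), log(1/3), rep(log(11/5), 3), rep(log(1/2), 3)))
  expect_equal(s10$beta_rc[2, ],
               c(log(7/5), log(1/2), rep(log(2), 3), rep(log(1/3), 3)))
  expect_null(s10$beta_cc)

  s5 <- scenario(5, K = 3)
  expect_equal(unname(s5$counts), c(0, 8, 8, 16))
  expect_null(s5$beta_rc)
  expect_equal(s5$beta_cc[1, ],
               c(log(6/5), log(5/6), rep(log(11/10), 3), rep(log(20/23), 3)))

  s1 <- scenario(1, K = 3)
  expect_equal(unname(s1$counts), c(6, 8, 2, 16))
  expect_equal(s1$beta_cc, rbind(c(log(11/10), log(2/3)),
                                 c(log(23/20), log(1/2))))
  expect_equal(s1$beta_rc[1, ],
               c(log(3/2), log(1/3), log(3/2), log(3/2), log(1/2), log(1/2)))

  expect_error(scenario(11), "unknown scenario id")
  expect_error(scenario(1, K = 4), "K must be")
  expect_error(scenario(1, rho = 1), "rho must lie")
})

test_that("K = 5 and K = 8 registries carry the printed effect vectors", {
  s5k5 <- scenario(10, K = 5)
  expect_equal(s5k5$alphas, c(-log(2.2), -log(2.1), -log(1.5), -log(1.2)))
  expect_equal(nrow(s5k5$beta_rc), 4)
  expect_equal(s5k5$beta_rc[4, ],
               c(log(17/10), log(10/17), rep(log(7/2), 3), rep(log(2/7), 3)))
  s7k5 <- scenario(7, K = 5)
  expect_equal(s7k5$beta_cc[3, ],
               c(log(23/20), log(20/23), log(23/20), log(6/5), log(6/5),
                 log(5/6), log(5/6), log(5/6)))

  s1k8 <- scenario(1, K = 8)
  expect_equal(s1k8$alphas,
               c(-log(2.2), -log(2.1), -log(1.5), -log(1.6), -log(2),
                 -log(1.8), -log(2.1)))
  expect_equal(nrow(s1k8$beta_rc), 7)
  expect_equal(s1k8$beta_rc[7, ],
               c(log(7/2), log(2/7), log(7/2), log(7/2), log(2/7), log(2/7)))
  expect_equal(s1k8$beta_cc[2, ], c(log(31/20), log(20/31)))
  s9k8 <- scenario(9, K = 8)
  expect_equal(s9k8$beta_rc[5, ],
               c(log(3), log(1/3), log(3), log(3), log(19/5), log(5/19),
                 log(1/3), log(1/3)))
})

test_that("raised-positive-proportion effect profiles are stored verbatim", {
  p75 <- scenario(10, K = 3, effect_profile = "75")
  expect_equal(p75$beta_rc[1, ],
               c(log(5/2), log(3), rep(log(11/5), 3), log(2), log(1/2), log(1/2)))
  expect_equal(p75$beta_rc[2, ],
               c(log(7/5), log(2), rep(log(2), 3), log(3), log(1/3), log(1/3)))
  p100 <- scenario(10, K = 3, effect_profile = "100")
  expect_equal(p100$beta_rc[1, ],
               c(log(5/2), log(3), rep(log(11/5), 3), rep(log(2), 3)))
  expect_equal(p100$beta_rc[2, ],
               c(log(7/5), log(2), rep(log(2), 3), rep(log(3), 3)))
  expect_true(all(p100$beta_rc > 0))
  expect_equal(mean(p75$beta_rc > 0), 0.75)
  expect_error(scenario(5, K = 3, effect_profile = "100"), "scenario 10")
})

test_that("MAF draws respect class ranges and the uniform mean", {
  cfg <- scenario(3, K = 3)
  set.seed(21)
  pos <- assign_positions(cfg)
  mafs <- draw_mafs(cfg, pos$classes)
  expect_length(mafs, cfg$m)
  for (cl in unique(pos$classes)) {
    r <- cfg$maf_ranges[[cl]]
    expect_true(all(mafs[pos$classes == cl] >= r[1] &
                    mafs[pos$classes == cl] <= r[2]))
  }
  # degenerate range draws the endpoint exactly
  degen <- list(counts = c(RC = 2, RNC = 0, CC = 0, CNC = 0),
                maf_ranges = list(RC = c(0.1, 0.1)))
  expect_equal(draw_mafs(degen), c(0.1, 0.1))
  # empirical mean of uniform(0.1, 0.3) draws
  unif <- list(counts = c(RC = 1, RNC = 0, CC = 0, CNC = 0),
               maf_ranges = list(RC = c(0.1, 0.3)))
  draws <- replicate(1e5, draw_mafs(unif))
  expect_lt(abs(mean(draws) - 0.2), 3 * 0.2 / sqrt(12 * 1e5))
})

test_that("class positions are a uniform arrangement with the right counts", {
  cfg <- scenario(10, K = 3)
  set.seed(22)
  pos <- assign_positions(cfg)
  expect_equal(sum(pos$causal_mask), 8)
  expect_equal(table(factor(pos$classes, c("RC", "RNC", "CC", "CNC"))),
               table(factor(rep(names(cfg$counts), cfg$counts),
                            c("RC", "RNC", "CC", "CNC"))))
  set.seed(99); a <- assign_positions(cfg)
  set.seed(99); b <- assign_positions(cfg)
  expect_identical(a, b)
  # exchangeability: position 1 is causal with frequency 8/32
  set.seed(23)
  hits <- replicate(2000, assign_positions(cfg)$causal_mask[1])
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
})

test_that("haplotype marginals, independence and LD match the latent model", {
  set.seed(31)
  mafs <- c(0.3, 0.1)
  # rho = 0: marginals at the MAFs, no cross-site correlation
  H <- simulate_haplotypes(mafs, c(TRUE, TRUE), rho = 0, count = 1e5)
  for (j in 1:2)
    expect_lt(abs(mean(H[, j]) - mafs[j]),
              3 * sqrt(mafs[j] * (1 - mafs[j]) / 1e5))
  expect_lt(abs(cor(H[, 1], H[, 2])), 3 / sqrt(1e5))
  # rho = 0.9 adjacent same-class sites: joint carrier probability matches
  # the bivariate-normal orthant value
  H9 <- simulate_haplotypes(c(0.3, 0.3), c(TRUE, TRUE), rho = 0.9, count = 1e5)
  p11 <- oracle_orthant(qnorm(0.3), qnorm(0.3), 0.9)
  expect_lt(abs(mean(H9[, 1] & H9[, 2]) - p11),
            3 * sqrt(p11 * (1 - p11) / 1e5))
  # cross-block (causal x non-causal) sites stay uncorrelated despite rho
  Hx <- simulate_haplotypes(c(0.3, 0.3), c(TRUE, FALSE), rho = 0.9, count = 1e5)
  expect_lt(abs(cor(Hx[, 1], Hx[, 2])), 3 / sqrt(1e5))
})

test_that("genotypes are sums of two haplotypes with Hardy-Weinberg margins", {
  set.seed(32)
  G <- simulate_genotypes(c(0.5, 0.5), c(TRUE, TRUE), rho = 0, count = 1e5)
  expect_true(all(G %in% 0:2))
  freq <- tabulate(G[, 1] + 1L, 3L) / 1e5
  hw <- c(0.25, 0.5, 0.25)
  for (g in 1:3)
    expect_lt(abs(freq[g] - hw[g]), 3 * sqrt(hw[g] * (1 - hw[g]) / 1e5))
  # vanishing MAF: genotypes almost surely zero
  G0 <- simulate_genotypes(c(1e-8, 1e-8), c(TRUE, TRUE), rho = 0, count = 1e4)
  expect_equal(sum(G0), 0)
  # zero draws: empty matrix with m columns
  expect_equal(dim(simulate_genotypes(c(0.1, 0.1), c(TRUE, TRUE), 0, 0)),
               c(0L, 2L))
})

test_that("trait simulation follows the baseline-category logit model", {
  # beta = 0, K = 3, alpha = (-log 4, -log 3): pi = (3, 4, 12) / 19
  X <- matrix(0, 5, 2)
  pr <- category_probs(X, c(-log(4), -log(3)), matrix(0, 2, 2))
  expect_equal(pr[1, ], c(3, 4, 12) / 19, tolerance = 1e-12)
  expect_equal(unname(rowSums(pr)), rep(1, 5))
  # alpha = 0, beta = 0, K = 2 -> (0.5, 0.5)
  expect_equal(category_probs(X, 0, matrix(0, 1, 2))[1, ], c(0.5, 0.5))
  # empirical category frequencies under the null intercepts
  set.seed(33)
  y <- simulate_trait(matrix(0, 2e5, 2), c(-log(4), -log(3)), matrix(0, 2, 2))
  pi0 <- c(3, 4, 12) / 19
  freq <- tabulate(y, 3) / 2e5
  for (k in 1:3)
    expect_lt(abs(freq[k] - pi0[k]), 3 * sqrt(pi0[k] * (1 - pi0[k]) / 2e5))
  expect_error(category_probs(matrix(2, 2, 2), c(1e309, 0), matrix(0, 2, 2)),
               "non-finite")
})

test_that("pools fix MAFs and positions; sampling and seeds are reproducible", {
  cfg <- scenario(10, K = 3, rho = 0.5, n_sample = 50, pool_size = 400)
  pool <- simulate_pool(cfg, seed = 7)
  expect_equal(dim(pool$geno), c(400L, 32L))
  expect_equal(sum(pool$causal_mask), 8)
  # realized effect matrix is zero off the causal sites, printed values on them
  expect_true(all(pool$beta[, !pool$causal_mask] == 0))
  expect_equal(pool$beta[, pool$causal_mask], cfg$beta_rc)
  # whole-pool sample is a permutation of the pool
  d <- sample_from_pool(pool, n = 400, seed = 1)
  expect_equal(sort(unname(rowSums(d$geno))), sort(unname(rowSums(pool$geno))))
  expect_error(sample_from_pool(pool, n = 401), "exceeds pool size")
  # end-to-end reproducibility
  d1 <- generate_dataset(cfg, seed = 42)
  d2 <- generate_dataset(cfg, seed = 42)
  expect_identical(d1$geno, d2$geno)
  expect_identical(d1$trait, d2$trait)
  expect_equal(dim(d1$geno), c(50L, 32L))
})

test_that("realized pool allele frequencies track the drawn MAFs", {
  cfg <- scenario(10, K = 3, rho = 0, pool_size = 1e5)
  pool <- simulate_pool(cfg, seed = 8)
  realized <- colMeans(pool$geno) / 2
  for (j in seq_along(pool$mafs)) {
    se <- sqrt(pool$mafs[j] * (1 - pool$mafs[j]) / (2 * 1e5))
    expect_lt(abs(realized[j] - pool$mafs[j]), 3 * se)
  }
})

test_that("under the null the trait is independent of every genotype column", {
  cfg <- scenario(10, K = 3, rho = 0.5, pool_size = 2e4)
  pool <- simulate_pool(cfg, seed = 9, null = TRUE)
  expect_true(all(pool$beta == 0))
  pvals <- vapply(seq_len(ncol(pool$geno)), function(j) {
    carrier <- pool$geno[, j] > 0
    if (sum(carrier) < 5) return(NA_real_)  # too sparse for the chi-square screen
    suppressWarnings(chisq.test(table(carrier, pool$trait))$p.value)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  rej <- sum(pvals <= 0.05)
  expect_lte(rej, ceiling(0.05 * length(pvals) + 3 * sqrt(length(pvals) * 0.05 * 0.95)))
})

test_that("scenario configs round-trip through the key=value file", {
  cfg <- scenario(10, K = 3, rho = 0.9, effect_profile = "100",
                  n_sample = 500, pool_size = 10000)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_scenario_config(cfg, path)
  expect_true(any(grepl("scenario_id=10", readLines(path))))
  back <- read_scenario_config(path)
  expect_equal(back, cfg)
  expect_error(read_scenario_config(withr::local_tempfile(lines = "K=3")),
               "missing keys")
})
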