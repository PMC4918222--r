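# Independent oracles and fixture builders. Every oracle is written as a
# naive literal transcription of the defining formulas (explicit loops, no
# sharing with the package's vectorized implementations).

# Four individuals, two sites, two categories: category 1 carries column
# sums (2, 0), category 2 carries (0, 2). Hand-computed statistics:
# MIT = 0.75 log(3/2) + 0.25 log(1/2) = 0.1308120...
# aMIT = (0.375 - 0.25) log(3/2) + (0.125 - 0.25) log(1/2) = 0.1373265...
toy_dataset <- function() {
  list(geno = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
       trait = c(1L, 1L, 2L, 2L))
}
TOY_MIT <- 0.75 * log(1.5) + 0.25 * log(0.5)
TOY_AMIT <- (0.375 - 0.25) * log(1.5) + (0.125 - 0.25) * log(0.5)

# Naive double-loop MIT/aMIT straight from the pseudocounted definitions.
oracle_mi <- function(X, y, K = max(y)) {
  n <- nrow(X); m <- ncol(X)
  ps <- numeric(m)
  for (j in 1:m) ps[j] <- sum(X[, j]) + 1
  ps <- ps / sum(ps)
  mit <- 0; amit <- 0
  for (k in 1:K) {
    pk <- sum(y == k) / n
    cnt <- numeric(m)
    for (j in 1:m) cnt[j] <- sum(X[y == k, j]) + 1
    pc <- cnt / sum(cnt)
    for (j in 1:m) {
      pjk <- pc[j] * pk
      mit <- mit + pjk * log(pjk / (ps[j] * pk))
      amit <- amit + 0.5 * (pjk - ps[j] * pk) * log(pjk / (ps[j] * pk))
    }
  }
  c(MIT = mit, aMIT = amit)
}

# Exhaustive permutation p-value on tiny n: every relabeling of y.
oracle_exhaustive_pvalue <- function(X, y, stat_fun) {
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  P <- perms(seq_along(y))
  t_obs <- stat_fun(X, y)
  mean(apply(P, 1L, function(ord) stat_fun(X, y[ord]) >= t_obs))
}

# Textbook binary logistic score test: z = I(y == 1), design W = (1, X),
# null fit p = mean(z), U = W'(z - p), I = p(1-p) W'W, stat = U' I^{-1} U.
oracle_binary_score <- function(X, y) {
  z <- as.numeric(y == 1)
  W <- cbind(1, X)
  p <- mean(z)
  U <- drop(t(W) %*% (z - p))
  I <- p * (1 - p) * crossprod(W)
  drop(t(U) %*% solve(I, U))
}

# Full-parameter multinomial score test, per-individual loops, no intercept
# profiling: theta = (alpha_k, beta_k) stacked k-major; at the null MLE the
# intercept scores vanish and U' I_full^{-1} U equals the efficient score
# statistic by the partitioned-inverse identity.
oracle_multinomial_score <- function(X, y, K = max(y)) {
  n <- nrow(X); m <- ncol(X)
  W <- cbind(1, X)
  p1 <- tabulate(y, K)[1:(K - 1)] / n
  V <- diag(p1, K - 1) - outer(p1, p1)
  d <- (K - 1) * (m + 1)
  U <- numeric(d); I <- matrix(0, d, d)
  for (i in 1:n) {
    e <- as.numeric(y[i] == seq_len(K - 1)) - p1
    U <- U + kronecker(e, W[i, ])
    I <- I + kronecker(V, outer(W[i, ], W[i, ]))
  }
  drop(t(U) %*% solve(I, U))
}

# Random non-degenerate genotype/trait instance with every category observed
# and every site polymorphic enough for full-rank designs when needed.
random_instance <- function(n, m, K, maf = 0.3) {
  repeat {
    X <- matrix(rbinom(n * m, 2, maf), n, m)
    y <- sample.int(K, n, replace = TRUE)
    if (length(unique(y)) == K) return(list(geno = X, trait = y))
  }
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature (conditional-normal decomposition).
oracle_orthant <- function(a, b, rho) {
  integrate(function(z) pnorm((b - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
            -Inf, a, rel.tol = 1e-10)$value
}
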