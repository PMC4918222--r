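#' Pseudocounted distribution of variant counts across sites
#'
#' The region statistic views the m sites as the support of a discrete random
#' variable S: site j carries probability proportional to its total
#' minor-allele count plus one. The added count of 1 per site guarantees a
#' strictly positive probability at every site, so monomorphic (all-zero)
#' columns remain well defined and are retained.
#'
#' @param geno genotype matrix (see [as_genotype_matrix()]).
#' @return numeric vector of length m summing to 1, named by site; attribute
#'   \code{condition} is \code{"unconditional"}.
#' @export
site_distribution <- function(geno) {
  geno <- as_genotype_matrix(geno)
  cnt <- colSums(geno) + 1
  p <- cnt / sum(cnt)
  attr(p, "condition") <- "unconditional"
  p
}

#' Site distribution conditional on a trait category
#'
#' Same pseudocounted construction as [site_distribution()], restricted to the
#' individuals whose trait value equals \code{k}. A stratum carrying no
#' minor alleles is still well defined (uniform over sites, from the
#' pseudocounts alone).
#'
#' @param geno genotype matrix.
#' @param trait categorical trait (see [as_trait_vector()]).
#' @param k category in 1..K; must be observed in the sample.
#' @return numeric vector of length m summing to 1; attribute
#'   \code{condition} records k.
#' @export
conditional_site_distribution <- function(geno, trait, k) {
  geno <- as_genotype_matrix(geno)
  trait <- as_trait_vector(trait, n = nrow(geno))
  K <- trait_K(trait)
  if (length(k) != 1L || k < 1 || k > K) stop("k must be a single category in 1..K")
  idx <- trait == k
  if (!any(idx)) stop("empty stratum: no individual with trait category ", k)
  cnt <- colSums(geno[idx, , drop = FALSE]) + 1
  p <- cnt / sum(cnt)
  attr(p, "condition") <- as.integer(k)
  p
}

#' Empirical trait distribution
#'
#' Empirical category proportions n_k / n, the maximum-likelihood estimate of
#' P(Y = k) used as the mixing weight in the mutual-information statistics.
#'
#' @param trait categorical trait vector.
#' @param K number of categories (defaults to the attribute / max label).
#' @return numeric vector of length K summing to 1.
#' @export
trait_distribution <- function(trait, K = NULL) {
  trait <- as_trait_vector(trait, K = K)
  tabulate(trait, nbins = trait_K(trait)) / length(trait)
}

#' Kullback-Leibler divergence between two site distributions
#'
#' KL(p, q) = sum_j p_j log(p_j / q_j). Asymmetric: KL(p, q) != KL(q, p) in
#' general, which motivates the symmetrized aMIT statistic. Natural logarithm
#' by default; the base rescales the value by a positive constant and leaves
#' permutation p-values unchanged.
#'
#' @param p,q probability vectors of equal length with strictly positive
#'   entries (pseudocounted site distributions satisfy this by construction).
#' @param base logarithm base.
#' @return nonnegative scalar; 0 iff p == q.
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p <= 0) || any(q <= 0)) stop("KL divergence requires strictly positive entries")
  sum(p * (log(p) - log(q))) / log(base)
}

## Both statistics from a K x m category-by-site count matrix N (no
## pseudocounts), the pooled column counts cs (no pseudocounts) and the trait
## proportions pk. Used by the exported statistics and, heavily, by the
## permutation loop where only N changes between permutations.
.mi_from_counts <- function(N, cs, pk, log_ps = NULL) {
  K <- length(pk)
  m <- length(cs)
  ps <- (cs + 1) / sum(cs + 1)
  if (is.null(log_ps)) log_ps <- log(ps)
  Np <- N + 1
  pc <- Np / rowSums(Np)                       # K x m conditional P(S=j | Y=k)
  lr <- log(pc) - matrix(log_ps, K, m, byrow = TRUE)
  mit <- sum(pk * rowSums(pc * lr))
  amit <- 0.5 * sum(pk * rowSums((pc - matrix(ps, K, m, byrow = TRUE)) * lr))
  c(MIT = mit, aMIT = amit)
}

.category_counts <- function(geno, trait, K) {
  N <- matrix(0, K, ncol(geno))
  have <- rowsum(geno, trait)                  # rows ordered by sort(unique(trait))
  N[sort(unique(trait)), ] <- have
  N
}

#' Mutual-information region statistic (MIT)
#'
#' The trait-weighted sum over categories of the Kullback-Leibler divergence
#' between the conditional site distribution given Y = k and the
#' unconditional site distribution:
#' MI(S, Y) = sum_k P(Y=k) KL(S|Y=k, S). Independence of S and Y gives 0;
#' larger values signal larger between-category differences in where the
#' minor alleles sit across the region.
#'
#' Because each distribution carries its own pseudocounts, the mixture of the
#' conditionals does not reduce exactly to the unconditional distribution, so
#' the value can differ slightly from a textbook mutual information; the
#' pseudocounted construction is applied literally.
#'
#' @param geno genotype matrix (n x m, entries 0/1/2).
#' @param trait categorical trait vector.
#' @param base logarithm base (default natural log).
#' @return nonnegative scalar.
#' @export
mit_statistic <- function(geno, trait, base = exp(1)) {
  geno <- as_genotype_matrix(geno)
  trait <- as_trait_vector(trait, n = nrow(geno))
  K <- trait_K(trait)
  stats <- .mi_from_counts(.category_counts(geno, trait, K),
                           colSums(geno), tabulate(trait, K) / length(trait))
  unname(stats["MIT"]) / log(base)
}

#' Symmetrized mutual-information region statistic (aMIT)
#'
#' KL divergence is asymmetric; aMIT averages the two directions,
#' aMI(S, Y) = (1/2) E_Y of KL(S|Y, S) + KL(S, S|Y):
#'   aMI(S, Y) = (1/2) sum_k sum_j (P(S=j, Y=k) - P(S=j) P(Y=k))
#'             log( P(S=j, Y=k) / (P(S=j) P(Y=k)) ),
#' with P(S=j, Y=k) = P(S=j | Y=k) P(Y=k). Every summand is nonnegative:
#' the difference and the log-ratio always share their sign.
#'
#' @inheritParams mit_statistic
#' @return nonnegative scalar.
#' @export
amit_statistic <- function(geno, trait, base = exp(1)) {
  geno <- as_genotype_matrix(geno)
  trait <- as_trait_vector(trait, n = nrow(geno))
  K <- trait_K(trait)
  stats <- .mi_from_counts(.category_counts(geno, trait, K),
                           colSums(geno), tabulate(trait, K) / length(trait))
  unname(stats["aMIT"]) / log(base)
}

## Permutation null draws for both statistics at once: B independent uniform
## shuffles of the trait labels with genotypes fixed. The unconditional site
## distribution and the trait proportions are permutation-invariant, so only
## the K x m category count matrix is recomputed per shuffle.
.permutation_null <- function(geno, trait, K, B) {
  n <- nrow(geno)
  cs <- colSums(geno)
  pk <- tabulate(trait, K) / n
  log_ps <- log((cs + 1) / sum(cs + 1))
  out <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("MIT", "aMIT")))
  for (b in seq_len(B)) {
    yp <- trait[sample.int(n)]
    out[b, ] <- .mi_from_counts(rowsum(geno, yp), cs, pk, log_ps)
  }
  out
}

#' Permutation p-value for MIT or aMIT
#'
#' Shuffles the trait labels of all individuals B times while keeping the
#' genotypes fixed, recomputes the statistic on each shuffle, and estimates
#' the p-value as the fraction of permuted statistics at least as large as
#' the observed one: p = sum_b I(T^(b) >= T) / B. Division is by B (not
#' B + 1), so an estimated p-value of exactly 0 is possible and is reported
#' as "p < 1/B" by the print method.
#'
#' @param geno genotype matrix.
#' @param trait categorical trait vector (K >= 2).
#' @param statistic \code{"MIT"} or \code{"aMIT"}.
#' @param B number of permutations (>= 1).
#' @param seed optional integer seed for the permutation stream.
#' @param base logarithm base for the statistic (p-values are base-invariant).
#' @return object of class \code{mi_test}: list with \code{statistic_name},
#'   \code{statistic}, \code{p_value}, \code{B}, \code{seed}.
#' @seealso [mi_region_test()] to obtain both tests from one shared set of
#'   permutations.
#' @export
permutation_pvalue <- function(geno, trait, statistic = c("MIT", "aMIT"),
                               B = 1000L, seed = NULL, base = exp(1)) {
  statistic <- match.arg(statistic)
  res <- mi_region_test(geno, trait, tests = statistic, B = B, seed = seed, base = base)
  res[[statistic]]
}

#' MIT and aMIT with one shared permutation stream
#'
#' Computes the requested statistics and their permutation p-values using a
#' single set of B trait shuffles (both statistics are functions of the same
#' category-by-site count matrix, so sharing the stream costs nothing and
#' keeps the two tests comparable replication by replication).
#'
#' @inheritParams permutation_pvalue
#' @param tests subset of \code{c("MIT", "aMIT")}.
#' @return named list of \code{mi_test} objects, one per requested test.
#' @export
mi_region_test <- function(geno, trait, tests = c("MIT", "aMIT"),
                           B = 1000L, seed = NULL, base = exp(1)) {
  tests <- match.arg(tests, c("MIT", "aMIT"), several.ok = TRUE)
  geno <- as_genotype_matrix(geno)
  trait <- as_trait_vector(trait, n = nrow(geno), min_K = 2L)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  K <- trait_K(trait)
  obs <- .mi_from_counts(.category_counts(geno, trait, K),
                         colSums(geno), tabulate(trait, K) / length(trait))
  if (!is.null(seed)) set.seed(seed)
  null <- .permutation_null(geno, trait, K, B)
  out <- lapply(tests, function(s) {
    structure(list(statistic_name = s,
                   statistic = unname(obs[s]) / log(base),
                   p_value = mean(null[, s] >= obs[s]),
                   B = B, seed = seed),
              class = "mi_test")
  })
  names(out) <- tests
  out
}

#' @export
print.mi_test <- function(x, ...) {
  cat(sprintf("%s region test (permutation, B = %d)\n", x$statistic_name, x$B))
  cat(sprintf("  statistic = %.6g\n", x$statistic))
  if (x$p_value == 0) {
    cat(sprintf("  p-value   < %.4g  (no permuted statistic reached the observed one)\n",
                1 / x$B))
  } else {
    cat(sprintf("  p-value   = %.4g\n", x$p_value))
  }
  invisible(x)
}
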