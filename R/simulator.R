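## Latent-Gaussian genotype simulator. Each haplotype arises from a
## multivariate normal vector Z with standard-normal marginals; within the
## causal block and within the non-causal block the correlation is
## rho^|j - j'| on the original site indices, and it is zero across the two
## blocks. Site j carries the minor allele iff Z_j < qnorm(MAF_j) (the
## lower-tail convention; either tail gives the same marginal law and the
## same within-block correlation). A genotype is the sum of two independent
## haplotypes. Traits follow the baseline-category logit model.

## Deterministic child seeds so that toggling one stage does not shift the
## random streams of the others (kept below 2^31).
.child_seeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw minor-allele frequencies for a scenario
#'
#' Each site's MAF is drawn uniformly from the range of its variant class
#' (rare causal, rare non-causal, common causal, common non-causal).
#'
#' @param config a [scenario()] configuration.
#' @param classes character vector of per-site class labels, as returned by
#'   [assign_positions()]; when \code{NULL} the canonical order
#'   RC, RNC, CC, CNC is used.
#' @return numeric vector of length m.
#' @export
draw_mafs <- function(config, classes = NULL) {
  if (is.null(classes))
    classes <- rep(names(config$counts), config$counts)
  vapply(classes, function(cl) {
    r <- config$maf_ranges[[cl]]
    if (is.null(r)) stop("scenario has no sites of class ", cl)
    runif(1, r[1], r[2])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Randomly place the variant classes across the region
#'
#' A uniformly random arrangement of the configured class counts across
#' positions 1..m.
#'
#' @param config a [scenario()] configuration.
#' @return list with \code{classes} (length-m labels in RC/RNC/CC/CNC) and
#'   \code{causal_mask} (TRUE at the RC and CC positions).
#' @export
assign_positions <- function(config) {
  classes <- sample(rep(names(config$counts), config$counts))
  list(classes = classes,
       causal_mask = classes %in% c("RC", "CC"))
}

## Upper-triangular Cholesky factor of the blockwise AR(1) latent covariance.
## Each block is a principal submatrix of a full AR(1) correlation matrix,
## hence positive definite; their direct sum is too.
.latent_chol <- function(m, causal_mask, rho) {
  idx <- seq_len(m)
  Sig <- rho ^ abs(outer(idx, idx, "-"))
  same <- outer(causal_mask, causal_mask, "==")
  Sig[!same] <- 0
  chol(Sig)
}

#' Simulate binary haplotypes
#'
#' Draws latent vectors Z ~ MVN(0, Sigma) with unit marginals and the
#' blockwise AR(1) covariance described in the package vignette, then
#' thresholds: site j carries the minor allele iff Z_j < qnorm(MAF_j).
#'
#' @param mafs length-m vector of minor-allele frequencies.
#' @param causal_mask length-m logical; correlation applies within the causal
#'   block and within the non-causal block only.
#' @param rho latent AR(1) correlation in [0, 1).
#' @param count number of haplotypes.
#' @return count x m 0/1 matrix.
#' @export
simulate_haplotypes <- function(mafs, causal_mask, rho, count = 1L) {
  m <- length(mafs)
  count <- as.integer(count)
  if (count == 0L) return(matrix(0, 0L, m))
  R <- .latent_chol(m, causal_mask, rho)
  Z <- matrix(rnorm(count * m), count, m) %*% R
  thr <- matrix(qnorm(mafs), count, m, byrow = TRUE)
  (Z < thr) + 0
}

#' Simulate diploid genotypes
#'
#' Each individual's genotype at a site is the sum of two independent
#' haplotypes drawn with the same MAFs and latent covariance.
#'
#' @inheritParams simulate_haplotypes
#' @param count number of individuals.
#' @return count x m matrix with entries in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(mafs, causal_mask, rho, count) {
  simulate_haplotypes(mafs, causal_mask, rho, count) +
    simulate_haplotypes(mafs, causal_mask, rho, count)
}

#' Category probabilities under the baseline-category logit model
#'
#' pi_k(X_i) = exp(alpha_k + X_i' beta_k) / (1 + sum_l exp(alpha_l + X_i' beta_l))
#' for k < K, with the baseline pi_K completing the unit sum.
#'
#' @param geno n x m genotype matrix.
#' @param alphas length K-1 intercepts.
#' @param betas (K-1) x m effect matrix.
#' @return n x K matrix of probabilities.
#' @export
category_probs <- function(geno, alphas, betas) {
  eta <- sweep(geno %*% t(betas), 2L, alphas, "+")
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  expo <- exp(eta)
  denom <- 1 + rowSums(expo)
  cbind(expo, 1) / denom
}

#' Simulate trait values from genotypes
#'
#' Draws each individual's category from the baseline-category logit
#' probabilities implied by its genotype.
#'
#' @inheritParams category_probs
#' @return integer trait vector in 1..K.
#' @export
simulate_trait <- function(geno, alphas, betas) {
  probs <- category_probs(geno, alphas, betas)
  K <- ncol(probs)
  cum <- probs %*% upper.tri(diag(K), diag = TRUE)   # row-wise cumulative sums
  as.integer(1L + rowSums(runif(nrow(probs)) > cum[, -K, drop = FALSE]))
}

## Assemble the realized (K-1) x m effect matrix: causal-class effect columns
## are placed at the causal positions in position order (RC entries at the RC
## sites, CC entries at the CC sites); non-causal columns are zero.
.full_beta <- function(config, classes) {
  beta <- matrix(0, config$K - 1L, length(classes))
  if (!is.null(config$beta_rc)) beta[, classes == "RC"] <- config$beta_rc
  if (!is.null(config$beta_cc)) beta[, classes == "CC"] <- config$beta_cc
  beta
}

#' Simulate a population pool for a scenario
#'
#' Draws the MAFs and the arrangement of variant classes once, then
#' simulates \code{config$pool_size} individuals (genotypes plus trait).
#' Monte-Carlo replications sample individuals from this fixed pool with
#' [sample_from_pool()]. Each simulation stage (positions, MAFs, haplotypes,
#' trait) runs on its own child stream of \code{seed}.
#'
#' @param config a [scenario()] configuration.
#' @param seed integer master seed.
#' @param null if TRUE, all effect vectors are forced to zero (type-I error
#'   conditions); the scenario's MAF ranges and class layout are unchanged.
#' @return object of class \code{simulated_pool}: list with \code{geno},
#'   \code{trait}, \code{classes}, \code{causal_mask}, \code{mafs},
#'   \code{beta}, \code{config}, \code{seed}.
#' @export
simulate_pool <- function(config, seed, null = FALSE) {
  seeds <- .child_seeds(seed, 6L)
  set.seed(seeds[1]); pos <- assign_positions(config)
  set.seed(seeds[2]); mafs <- draw_mafs(config, pos$classes)
  beta <- .full_beta(config, pos$classes)
  if (null) beta[] <- 0
  set.seed(seeds[3])
  geno <- simulate_genotypes(mafs, pos$causal_mask, config$rho, config$pool_size)
  colnames(geno) <- paste0("site", seq_len(config$m))
  set.seed(seeds[4])
  trait <- simulate_trait(geno, config$alphas, beta)
  structure(list(geno = geno, trait = trait,
                 classes = pos$classes, causal_mask = pos$causal_mask,
                 mafs = mafs, beta = beta, config = config, seed = seed),
            class = "simulated_pool")
}

#' Sample individuals from a simulated pool
#'
#' Uniform sampling without replacement, the per-replication step of the
#' Monte-Carlo design.
#'
#' @param pool a [simulate_pool()] object.
#' @param n sample size (defaults to the scenario's \code{n_sample}).
#' @param seed optional seed; when \code{NULL} the current RNG stream is used.
#' @return object of class \code{simulated_dataset}: list with \code{geno}
#'   (n x m, row names \code{ind<i>}), \code{trait}, \code{causal_mask},
#'   \code{mafs}, \code{seed}.
#' @export
sample_from_pool <- function(pool, n = NULL, seed = NULL) {
  if (is.null(n)) n <- pool$config$n_sample
  pool_n <- nrow(pool$geno)
  if (n > pool_n) stop("n_sample (", n, ") exceeds pool size (", pool_n, ")")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(pool_n, n)
  geno <- pool$geno[idx, , drop = FALSE]
  rownames(geno) <- paste0("ind", seq_len(n))
  structure(list(geno = geno, trait = pool$trait[idx],
                 classes = pool$classes, causal_mask = pool$causal_mask,
                 mafs = pool$mafs, seed = seed),
            class = "simulated_dataset")
}

#' Generate one dataset under a scenario
#'
#' End-to-end convenience: build a pool with [simulate_pool()] and draw one
#' sample of \code{config$n_sample} individuals from it.
#'
#' @inheritParams simulate_pool
#' @return a \code{simulated_dataset} (see [sample_from_pool()]).
#' @export
generate_dataset <- function(config, seed, null = FALSE) {
  seeds <- .child_seeds(seed, 6L)
  pool <- simulate_pool(config, seed, null = null)
  out <- sample_from_pool(pool, seed = seeds[5])
  out$seed <- seed
  out
}
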