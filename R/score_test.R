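#' Baseline-category-logit score test for a region
#'
#' Parametric comparator to the mutual-information tests. The trait is
#' modelled by a baseline-category (multinomial) logit with the last
#' category as baseline,
#' \deqn{\log \pi_k(X_i) / \pi_K(X_i) = \alpha_k + X_i' \beta_k,
#'       \quad k = 1, \dots, K - 1,}
#' and the null hypothesis is beta_1 = ... = beta_{K-1} = 0. Only the null
#' fit is needed: the null MLE is intercept-only, with fitted probabilities
#' pi_k = n_k / n for every individual.
#'
#' The intercepts are profiled out at the null, which amounts to centering
#' every genotype column at its sample mean. Writing Xc for the centered
#' matrix, the efficient score for the stacked slopes is
#' U = (U_1', ..., U_{K-1}')' with U_k = Xc' (I(Y = k) - pi_k), and the
#' efficient information factorizes as V \%x\% (Xc' Xc) where
#' V = diag(pi) - pi pi' over the K - 1 non-baseline categories. The
#' statistic U' I^- U is compared with a chi-square on m (K - 1) degrees of
#' freedom (reduced when the centered design is rank deficient, as happens
#' with constant or collinear rare-variant columns: the information is
#' inverted by an eigenvalue-thresholded pseudo-inverse and the retained
#' rank drives the degrees of freedom).
#'
#' @param geno genotype matrix (n x m, minor-allele counts).
#' @param trait categorical trait with K >= 2 observed categories.
#' @param tol relative eigenvalue threshold for the pseudo-inverse of
#'   Xc'Xc (times its largest eigenvalue).
#' @return object of class \code{score_test}: list with \code{statistic},
#'   \code{df}, \code{p_value}, \code{dropped_sites} (ids of constant
#'   columns, which contribute nothing to the test), \code{rank}.
#' @export
score_statistic <- function(geno, trait, tol = 1e-10) {
  geno <- as_genotype_matrix(geno)
  trait <- as_trait_vector(trait, n = nrow(geno), min_K = 2L)
  n <- nrow(geno); m <- ncol(geno)
  K <- trait_K(trait)
  if (n <= m * (K - 1))
    warning("n <= m(K-1): the chi-square approximation may be poor")

  pik <- tabulate(trait, K) / n
  p1 <- pik[seq_len(K - 1)]
  Xc <- sweep(geno, 2L, colMeans(geno), "-")
  const <- colSums(Xc * Xc) == 0
  # efficient score, k-major stacking
  U <- vapply(seq_len(K - 1),
              function(k) colSums(Xc * ((trait == k) - p1[k])),
              numeric(m))                       # m x (K-1)
  V <- diag(p1, K - 1) - tcrossprod(p1)         # (K-1) x (K-1), PD when all n_k > 0
  Sxx <- crossprod(Xc)

  es <- eigen(Sxx, symmetric = TRUE)
  keep <- es$values > tol * max(es$values, 0)
  r <- sum(keep)
  if (r == 0L)
    stop("degenerate design: no genotype variation at any site")
  # Sxx^+ restricted to the retained eigenspace
  Vec <- es$vectors[, keep, drop = FALSE]
  Sxx_pinv <- Vec %*% (t(Vec) / es$values[keep])
  Vinv <- solve(V)
  # U' (V^{-1} (x) Sxx^+) U with U stored as m x (K-1): trace form
  stat <- sum((Sxx_pinv %*% U) * (U %*% t(Vinv)))
  df <- r * (K - 1)

  structure(list(statistic = stat,
                 df = as.integer(df),
                 p_value = pchisq(stat, df = df, lower.tail = FALSE),
                 dropped_sites = colnames(geno)[const],
                 rank = as.integer(r),
                 K = K, m = m, n = n),
            class = "score_test")
}

#' @export
print.score_test <- function(x, ...) {
  cat("Baseline-category-logit score test\n")
  cat(sprintf("  statistic = %.6g on %d df (chi-square), p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$dropped_sites))
    cat("  constant sites carrying no information:",
        paste(x$dropped_sites, collapse = ", "), "\n")
  invisible(x)
}
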