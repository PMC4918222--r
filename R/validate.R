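#' Validate and normalize a genotype matrix
#'
#' A region's genotypes are an n x m integer matrix whose entry (i, j) is the
#' number of copies (0, 1 or 2) of the minor allele carried by individual i
#' at variant site j. The tests in this package are defined for regions with
#' at least two sites; a single-site region is refused.
#'
#' @param x matrix (or coercible) of minor-allele counts in \{0, 1, 2\};
#'   rows are individuals, columns are variant sites.
#' @return a numeric matrix with row and column names filled in
#'   (\code{ind1..indn}, \code{site1..sitem} when absent).
#' @export
as_genotype_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("genotypes must be numeric minor-allele counts")
  if (anyNA(x)) stop("genotype matrix contains missing values; resolve missingness at ingestion")
  if (nrow(x) < 1L) stop("genotype matrix needs at least one individual")
  if (ncol(x) < 2L) stop("region too small: tests require m >= 2 variant sites")
  if (!all(x %in% c(0, 1, 2)))
    stop("genotype entries must be minor-allele copy numbers in {0, 1, 2}")
  if (is.null(colnames(x))) colnames(x) <- paste0("site", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  storage.mode(x) <- "double"
  x
}

#' Validate and normalize a categorical trait vector
#'
#' Trait values are nominal category labels 1..K. Labels supplied as a factor
#' or as arbitrary sorted-unique values are recoded to consecutive integers.
#'
#' @param labels vector of category labels (integer codes 1..K, or a factor).
#' @param K number of categories; defaults to the number of distinct labels.
#'   Every category 1..K must be observed at least once.
#' @param n expected length (optional; checked when supplied).
#' @param min_K minimum admissible number of categories (the association
#'   tests need K >= 2; the bare statistics are defined for K = 1).
#' @return integer vector in 1..K with attribute \code{K}.
#' @export
as_trait_vector <- function(labels, K = NULL, n = NULL, min_K = 1L) {
  if (is.factor(labels)) labels <- as.integer(labels)
  if (anyNA(labels)) stop("trait vector contains missing values")
  labels <- as.integer(labels)
  if (is.null(K)) K <- max(labels)
  if (!is.null(n) && length(labels) != n)
    stop("trait length (", length(labels), ") does not match genotype rows (", n, ")")
  if (any(labels < 1L | labels > K))
    stop("trait labels must lie in 1..K")
  if (K < min_K) stop("trait must have at least ", min_K, " categories")
  counts <- tabulate(labels, nbins = K)
  if (any(counts == 0L))
    stop("empty stratum: every category 1..K must be observed at least once")
  attr(labels, "K") <- as.integer(K)
  labels
}

trait_K <- function(trait) {
  K <- attr(trait, "K")
  if (is.null(K)) K <- max(trait)
  as.integer(K)
}
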