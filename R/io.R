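#' Write a genotype matrix as TSV
#'
#' Plain tab-separated matrix: header \code{individual_id} plus one column
#' per site id; one row per individual with minor-allele counts.
#'
#' @param geno genotype matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  geno <- as_genotype_matrix(geno)
  df <- data.frame(individual_id = rownames(geno), geno,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Expects the layout written by [write_genotypes_tsv()]. Entries must be
#' minor-allele counts in \{0, 1, 2\}; missing entries are imputed to 0
#' copies with a warning (or the individuals dropped, per
#' \code{missing = "drop"}).
#'
#' @param path TSV file.
#' @param missing \code{"impute0"} (default) or \code{"drop"}.
#' @return genotype matrix with individual ids as row names.
#' @export
read_genotypes_tsv <- function(path, missing = c("impute0", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!"individual_id" %in% names(df))
    stop("genotype TSV must have an 'individual_id' column: ", path)
  ids <- df$individual_id
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  x <- as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE])
  suppressWarnings(storage.mode(x) <- "double")
  rownames(x) <- ids
  x <- .resolve_missing(x, missing, path)
  as_genotype_matrix(x)
}

.resolve_missing <- function(x, missing, src) {
  if (!anyNA(x)) return(x)
  if (missing == "impute0") {
    warning(sum(is.na(x)), " missing genotype(s) in ", src,
            " imputed to 0 copies")
    x[is.na(x)] <- 0
  } else {
    bad <- apply(is.na(x), 1L, any)
    warning("dropping ", sum(bad), " individual(s) with missing genotypes in ", src)
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Read a categorical phenotype TSV
#'
#' Two tab-separated columns, \code{individual_id} and \code{category};
#' labels may be arbitrary strings or integers (e.g. an affection scale
#' coded 1/3/5) and are mapped to 1..K by sorted order. Individuals with a
#' missing label are dropped with a warning.
#'
#' @param path TSV file.
#' @return integer trait vector (attribute \code{K}) named by individual id,
#'   with the label mapping in attribute \code{label_map}.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("individual_id", "category") %in% names(df)))
    stop("phenotype TSV must have 'individual_id' and 'category' columns: ", path)
  keep <- !is.na(df$category) & nzchar(df$category)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " individual(s) with missing phenotype in ", path)
    df <- df[keep, , drop = FALSE]
  }
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids in ", path)
  labels <- sort(unique(df$category))
  if (length(labels) < 2L)
    stop("phenotype must have at least 2 distinct categories after dropping missing labels")
  y <- match(df$category, labels)
  message("phenotype label mapping: ",
          paste(sprintf("%s -> %d", labels, seq_along(labels)), collapse = ", "))
  y <- as_trait_vector(y, K = length(labels), min_K = 2L)
  names(y) <- df$individual_id
  attr(y, "label_map") <- setNames(seq_along(labels), labels)
  y
}

#' Write a phenotype TSV
#'
#' @param trait trait vector; names are used as individual ids (defaults to
#'   \code{ind<i>}).
#' @param path output file.
#' @export
write_phenotype_tsv <- function(trait, path) {
  ids <- names(trait)
  if (is.null(ids)) ids <- paste0("ind", seq_along(trait))
  df <- data.frame(individual_id = ids, category = as.integer(trait))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' One record per site on a synthetic chromosome (CHROM 1, POS 1..m,
#' REF A / ALT C), GT-only FORMAT, unphased diploid calls, one sample column
#' per individual. The output is plain text (uncompressed), re-readable by
#' [read_genotypes_vcf()].
#'
#' @param geno genotype matrix (counts of the ALT allele).
#' @param path output file.
#' @export
write_genotypes_vcf <- function(geno, path) {
  geno <- as_genotype_matrix(geno)
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=micat",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  records <- vapply(seq_len(ncol(geno)), function(j) {
    paste(c("1", j, colnames(geno)[j], "A", "C", ".", "PASS", ".", "GT",
            gt_str[geno[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Reads diploid GT fields via \pkg{vcfR} and counts copies of the ALT
#' allele, then re-orients each site so that the counted allele is the
#' sample minor allele (frequency <= 0.5; exact ties keep the file's ALT
#' allele) — the region statistics are not invariant to allele flips, so
#' the orientation convention must be explicit. Flipped sites are reported
#' in a message. Multiallelic records and non-diploid calls are refused;
#' missing calls follow the \code{missing} policy.
#'
#' @param path VCF file (plain or bgzipped).
#' @param missing \code{"impute0"} (default) or \code{"drop"}.
#' @return genotype matrix (individuals x sites).
#' @export
read_genotypes_vcf <- function(path, missing = c("impute0", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multiallelic VCF records are not supported; split them first")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  counts <- apply(gt, c(1, 2), .gt_to_count)
  x <- t(counts)
  colnames(x) <- ids
  x <- .resolve_missing(x, missing, path)
  orient_minor_allele(as_genotype_matrix(x))
}

.gt_to_count <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("0", "1", ".")))
    stop("unsupported GT field: ", g)
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Re-orient counted alleles to the sample minor allele
#'
#' For every site whose counted-allele sample frequency exceeds 0.5, counts
#' are flipped (x -> 2 - x). Ties at exactly 0.5 are left as read.
#'
#' @param geno genotype matrix.
#' @return genotype matrix with all counted-allele frequencies <= 0.5;
#'   flipped site ids in attribute \code{flipped}.
#' @export
orient_minor_allele <- function(geno) {
  geno <- as_genotype_matrix(geno)
  freq <- colMeans(geno) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    message("re-orienting ", sum(flip), " site(s) to the sample minor allele: ",
            paste(colnames(geno)[flip], collapse = ", "))
    geno[, flip] <- 2 - geno[, flip]
  }
  attr(geno, "flipped") <- colnames(geno)[flip]
  geno
}

#' Read genotypes from TSV or VCF
#'
#' Dispatches on the file extension: \code{.vcf} / \code{.vcf.gz} to the VCF
#' reader, anything else to the TSV reader.
#'
#' @inheritParams read_genotypes_tsv
#' @export
read_genotypes <- function(path, missing = "impute0") {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    read_genotypes_vcf(path, missing = missing)
  else
    read_genotypes_tsv(path, missing = missing)
}

#' Region association test from files
#'
#' Reads genotypes (TSV or VCF) and a phenotype TSV, intersects individuals
#' by id (order-independent), optionally drops monomorphic sites, and runs
#' the requested tests.
#'
#' @param geno_path genotype TSV or VCF.
#' @param pheno_path phenotype TSV.
#' @param tests subset of \code{c("MIT", "aMIT", "Score")}.
#' @param B permutations for MIT/aMIT.
#' @param seed seed for the permutation stream.
#' @param drop_monomorphic drop sites with no variation before testing
#'   (off by default: the pseudocounted statistics handle them, and dropping
#'   changes m).
#' @param missing missingness policy for genotypes.
#' @return named list of test results (\code{mi_test} / \code{score_test}).
#' @export
region_test <- function(geno_path, pheno_path,
                        tests = c("MIT", "aMIT", "Score"),
                        B = 1000L, seed = NULL,
                        drop_monomorphic = FALSE, missing = "impute0") {
  tests <- match.arg(tests, c("MIT", "aMIT", "Score"), several.ok = TRUE)
  geno <- read_genotypes(geno_path, missing = missing)
  pheno <- read_phenotype(pheno_path)
  common <- intersect(rownames(geno), names(pheno))
  if (length(common) < 2L)
    stop("fewer than 2 individuals shared between genotype and phenotype files")
  geno <- geno[common, , drop = FALSE]
  y <- pheno[common]
  # re-validate: every category must survive the intersection
  labels <- sort(unique(y))
  y <- as_trait_vector(match(y, labels), K = length(labels), min_K = 2L)
  if (drop_monomorphic) {
    mono <- apply(geno, 2L, function(col) length(unique(col)) == 1L)
    if (any(mono)) {
      message("dropping ", sum(mono), " monomorphic site(s)")
      geno <- geno[, !mono, drop = FALSE]
    }
    if (ncol(geno) < 2L) stop("region too small after monomorphic-site filter")
  }
  out <- list()
  mi <- intersect(tests, c("MIT", "aMIT"))
  if (length(mi)) out <- mi_region_test(geno, y, tests = mi, B = B, seed = seed)
  if ("Score" %in% tests) out$Score <- score_statistic(geno, y)
  out
}
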