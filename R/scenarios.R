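## Benchmark scenario registry: ten configurations of rare-causal (RC),
## rare-non-causal (RNC), common-causal (CC) and common-non-causal (CNC)
## variant counts with per-class MAF ranges, plus the baseline-category-logit
## intercepts and per-class causal effect vectors for K = 3, 5 and 8.
## Effect entries are stored as exact log-ratio expressions.

.scenario_table <- data.frame(
  id   = 1:10,
  RC   = c(6, 6, 6, 6, 0, 8, 0, 8, 8, 8),
  RNC  = c(8, 16, 8, 8, 8, 16, 8, 16, 24, 24),
  CC   = c(2, 2, 2, 2, 8, 0, 8, 0, 0, 0),
  CNC  = c(16, 8, 8, 8, 16, 8, 16, 8, 0, 0)
)

.maf_ranges <- list(
  `1`  = list(RC = c(0.005, 0.01), RNC = c(0.005, 0.01), CC = c(0.1, 0.3), CNC = c(0.2, 0.5)),
  `2`  = list(RC = c(0.005, 0.01), RNC = c(0.01, 0.05),  CC = c(0.1, 0.3), CNC = c(0.1, 0.3)),
  `3`  = list(RC = c(0.005, 0.01), RNC = c(0.01, 0.05),  CC = c(0.1, 0.3), CNC = c(0.2, 0.5)),
  `4`  = list(RC = c(0.005, 0.01), RNC = c(0.005, 0.01), CC = c(0.1, 0.3), CNC = c(0.1, 0.3)),
  `5`  = list(RC = NULL,           RNC = c(0.005, 0.01), CC = c(0.1, 0.3), CNC = c(0.2, 0.5)),
  `6`  = list(RC = c(0.005, 0.01), RNC = c(0.01, 0.05),  CC = NULL,        CNC = c(0.1, 0.3)),
  `7`  = list(RC = NULL,           RNC = c(0.005, 0.01), CC = c(0.1, 0.3), CNC = c(0.1, 0.3)),
  `8`  = list(RC = c(0.005, 0.01), RNC = c(0.005, 0.01), CC = NULL,        CNC = c(0.1, 0.3)),
  `9`  = list(RC = c(0.005, 0.01), RNC = c(0.005, 0.01), CC = NULL,        CNC = NULL),
  `10` = list(RC = c(0.005, 0.01), RNC = c(0.01, 0.05),  CC = NULL,        CNC = NULL)
)

.alphas <- list(
  `3` = c(-log(4), -log(3)),
  `5` = c(-log(2.2), -log(2.1), -log(1.5), -log(1.2)),
  `8` = c(-log(2.2), -log(2.1), -log(1.5), -log(1.6), -log(2), -log(1.8), -log(2.1))
)

## Causal effect vectors, one row per non-baseline category, stacked by
## scenario family: scenarios 1-4 carry 6 RC + 2 CC causal variants;
## 6/8/9/10 carry 8 RC; 5/7 carry 8 CC.
.rbind_betas <- function(...) do.call(rbind, list(...))

.betas_K3 <- list(
  rc6 = .rbind_betas(
    c(log(3/2), log(1/3), log(3/2), log(3/2), log(1/2), log(1/2)),
    c(log(5/4), log(1/2), log(5/4), log(5/4), log(1/3), log(1/3))),
  cc2 = .rbind_betas(
    c(log(11/10), log(2/3)),
    c(log(23/20), log(1/2))),
  rc8 = .rbind_betas(
    c(log(5/2), log(1/3), log(11/5), log(11/5), log(11/5), log(1/2), log(1/2), log(1/2)),
    c(log(7/5), log(1/2), log(2),    log(2),    log(2),    log(1/3), log(1/3), log(1/3))),
  cc8 = .rbind_betas(
    c(log(6/5), log(5/6), log(11/10), log(11/10), log(11/10), log(20/23), log(20/23), log(20/23)),
    c(log(5/4), log(4/5), log(6/5),   log(6/5),   log(6/5),   log(10/13), log(10/13), log(10/13)))
)

## Scenario-10 effect vectors with raised proportions of positive components
## (75% and 100% of the causal effects risk-increasing), K = 3 only.
.betas_K3_profiles <- list(
  `75` = .rbind_betas(
    c(log(5/2), log(3), log(11/5), log(11/5), log(11/5), log(2), log(1/2), log(1/2)),
    c(log(7/5), log(2), log(2),    log(2),    log(2),    log(3), log(1/3), log(1/3))),
  `100` = .rbind_betas(
    c(log(5/2), log(3), log(11/5), log(11/5), log(11/5), log(2), log(2), log(2)),
    c(log(7/5), log(2), log(2),    log(2),    log(2),    log(3), log(3), log(3)))
)

.betas_K5 <- list(
  rc6 = .rbind_betas(
    .betas_K3$rc6[1, ],
    .betas_K3$rc6[2, ],
    c(log(27/20), log(2/5),   log(27/20), log(27/20), log(2/5),   log(2/5)),
    c(log(17/10), log(10/17), log(17/10), log(17/10), log(10/17), log(10/17))),
  cc2 = .rbind_betas(
    .betas_K3$cc2[1, ],
    .betas_K3$cc2[2, ],
    c(log(23/20), log(20/23)),
    c(log(6/5),   log(5/11))),
  rc8 = .rbind_betas(
    c(log(3/2),   log(1/3),   log(2),   log(2),   log(2),   log(1/2), log(1/2), log(1/2)),
    c(log(5/4),   log(1/2),   log(3),   log(3),   log(3),   log(1/3), log(1/3), log(1/3)),
    c(log(27/20), log(2/5),   log(5/2), log(5/2), log(5/2), log(2/5), log(2/5), log(2/5)),
    c(log(17/10), log(10/17), log(7/2), log(7/2), log(7/2), log(2/7), log(2/7), log(2/7))),
  cc8 = .rbind_betas(
    c(log(6/5),   log(6/5),   log(23/20), log(23/20), log(23/20), log(20/23), log(20/23), log(20/23)),
    c(log(23/20), log(1/2),   log(28/25), log(28/25), log(28/25), log(25/28), log(25/28), log(25/28)),
    c(log(23/20), log(20/23), log(23/20), log(6/5),   log(6/5),   log(5/6),   log(5/6),   log(5/6)),
    c(log(6/5),   log(5/11),  log(6/5),   log(6/5),   log(6/5),   log(10/13), log(10/13), log(10/13)))
)

.betas_K8 <- list(
  rc6 = .rbind_betas(
    c(log(3),     log(1/3),   log(16/5),  log(16/5),  log(5/16),  log(5/16)),
    c(log(3),     log(1/3),   log(3),     log(3),     log(1/3),   log(1/3)),
    c(log(5/2),   log(2/5),   log(5/2),   log(5/2),   log(2/5),   log(2/5)),
    c(log(17/10), log(10/17), log(13/10), log(13/10), log(10/13), log(10/13)),
    c(log(3),     log(1/3),   log(3),     log(3),     log(1/3),   log(1/3)),
    c(log(27/20), log(20/27), log(14/5),  log(14/5),  log(5/14),  log(5/14)),
    c(log(7/2),   log(2/7),   log(7/2),   log(7/2),   log(2/7),   log(2/7))),
  cc2 = .rbind_betas(
    c(log(3/2),   log(2/3)),
    c(log(31/20), log(20/31)),
    c(log(23/20), log(20/23)),
    c(log(6/5),   log(5/6)),
    c(log(23/20), log(20/23)),
    c(log(6/5),   log(5/6)),
    c(log(3/2),   log(2/3))),
  rc8 = .rbind_betas(
    c(log(19/5),  log(5/19),  log(16/5),  log(16/5),  log(16/5),  log(5/16),  log(5/16),  log(5/16)),
    c(log(9/2),   log(2/9),   log(3),     log(3),     log(3),     log(1/3),   log(1/3),   log(1/3)),
    c(log(4),     log(1/4),   log(5/2),   log(5/2),   log(5/2),   log(2/5),   log(2/5),   log(2/5)),
    c(log(17/10), log(10/17), log(13/10), log(13/10), log(13/10), log(10/13), log(10/13), log(10/13)),
    c(log(3),     log(1/3),   log(3),     log(3),     log(19/5),  log(5/19),  log(1/3),   log(1/3)),
    c(log(27/20), log(2/5),   log(14/5),  log(14/5),  log(14/5),  log(5/14),  log(5/14),  log(5/14)),
    c(log(7/2),   log(2/7),   log(7/2),   log(7/2),   log(7/2),   log(2/7),   log(2/7),   log(2/7))),
  cc8 = .rbind_betas(
    c(log(3/2),   log(2/3),   log(5/4),   log(5/4),   log(5/4),   log(4/5),   log(4/5),   log(4/5)),
    c(log(31/20), log(20/31), log(31/20), log(31/20), log(31/20), log(20/31), log(20/31), log(20/31)),
    c(log(23/20), log(20/23), log(23/20), log(23/20), log(23/20), log(20/23), log(20/23), log(20/23)),
    c(log(6/5),   log(5/6),   log(6/5),   log(6/5),   log(6/5),   log(5/6),   log(5/6),   log(5/6)),
    c(log(23/20), log(20/23), log(23/20), log(23/20), log(23/20), log(20/23), log(20/23), log(20/23)),
    c(log(6/5),   log(5/6),   log(6/5),   log(6/5),   log(6/5),   log(5/6),   log(5/6),   log(5/6)),
    c(log(3/2),   log(2/3),   log(13/10), log(13/10), log(13/10), log(10/13), log(10/13), log(10/13)))
)

.causal_betas <- function(id, K, effect_profile) {
  betas <- switch(as.character(K), `3` = .betas_K3, `5` = .betas_K5, `8` = .betas_K8)
  if (effect_profile != "default") {
    if (!(id == 10L && K == 3L))
      stop("effect profiles '75' and '100' are defined for scenario 10 with K = 3 only")
    return(list(RC = .betas_K3_profiles[[effect_profile]], CC = NULL))
  }
  if (id %in% c(1L, 2L, 3L, 4L)) list(RC = betas$rc6, CC = betas$cc2)
  else if (id %in% c(6L, 8L, 9L, 10L)) list(RC = betas$rc8, CC = NULL)
  else list(RC = NULL, CC = betas$cc8)
}

#' Benchmark simulation scenario
#'
#' Returns the full configuration of one of the ten registered benchmark
#' scenarios: counts of rare-causal (RC), rare-non-causal (RNC),
#' common-causal (CC) and common-non-causal (CNC) variants, per-class MAF
#' ranges, the latent AR(1) linkage-disequilibrium parameter rho, the
#' baseline-category-logit intercepts for the chosen number of trait
#' categories, and the causal effect vectors (stored per causal class; the
#' realized (K-1) x m matrix is assembled once positions are drawn).
#'
#' @param id scenario id, 1-10.
#' @param K number of trait categories: 3, 5 or 8.
#' @param rho latent AR(1) correlation in [0, 1); benchmark values are 0,
#'   0.5 and 0.9.
#' @param effect_profile \code{"default"} for the registered effect vectors;
#'   \code{"75"} or \code{"100"} select the scenario-10, K = 3 variants in
#'   which 75% resp. 100% of the causal effect components are positive.
#' @param n_sample individuals drawn per replication (benchmark: 1000).
#' @param pool_size size of the simulated population pool from which samples
#'   are drawn (default 200000; the benchmark value 2e6 is configurable).
#' @return object of class \code{scenario_config}.
#' @export
scenario <- function(id, K = 3, rho = 0, effect_profile = c("default", "75", "100"),
                     n_sample = 1000L, pool_size = 200000L) {
  effect_profile <- match.arg(effect_profile)
  id <- as.integer(id); K <- as.integer(K)
  if (!id %in% 1:10) stop("unknown scenario id: ", id)
  if (!K %in% c(3L, 5L, 8L)) stop("K must be 3, 5 or 8")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  row <- .scenario_table[id, ]
  counts <- c(RC = row$RC, RNC = row$RNC, CC = row$CC, CNC = row$CNC)
  betas <- .causal_betas(id, K, effect_profile)
  cfg <- list(scenario_id = id, K = K, rho = rho,
              effect_profile = effect_profile,
              counts = counts, m = sum(counts),
              maf_ranges = .maf_ranges[[as.character(id)]],
              alphas = .alphas[[as.character(K)]],
              beta_rc = betas$RC, beta_cc = betas$CC,
              n_sample = as.integer(n_sample),
              pool_size = as.integer(pool_size))
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %d (K = %d, rho = %g, effects: %s)\n",
              x$scenario_id, x$K, x$rho, x$effect_profile))
  cat(sprintf("  m = %d sites: %d RC, %d RNC, %d CC, %d CNC\n",
              x$m, x$counts["RC"], x$counts["RNC"], x$counts["CC"], x$counts["CNC"]))
  for (cl in names(x$maf_ranges)) {
    r <- x$maf_ranges[[cl]]
    if (!is.null(r)) cat(sprintf("  MAF %s: %g-%g\n", cl, r[1], r[2]))
  }
  cat(sprintf("  pool %d, sample %d\n", x$pool_size, x$n_sample))
  invisible(x)
}

#' Serialize a scenario configuration as flat key=value text
#'
#' Writes the identifying fields (id, K, rho, effect profile, sample and
#' pool sizes); the registry reconstructs everything else, so the file stays
#' a small, diffable record of the study conditions.
#'
#' @param config a [scenario()] configuration.
#' @param path output file.
#' @export
write_scenario_config <- function(config, path) {
  writeLines(c(paste0("scenario_id=", config$scenario_id),
               paste0("K=", config$K),
               paste0("rho=", format(config$rho, digits = 15)),
               paste0("effect_profile=", config$effect_profile),
               paste0("n_sample=", config$n_sample),
               paste0("pool_size=", config$pool_size)),
             path)
  invisible(path)
}

#' Read a scenario configuration from flat key=value text
#'
#' @param path file written by [write_scenario_config()].
#' @return a \code{scenario_config} rebuilt through the registry.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  vals <- setNames(kv[, 2], kv[, 1])
  need <- c("scenario_id", "K", "rho", "effect_profile", "n_sample", "pool_size")
  if (!all(need %in% names(vals)))
    stop("scenario config is missing keys: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  scenario(as.integer(vals["scenario_id"]), K = as.integer(vals["K"]),
           rho = as.numeric(vals["rho"]),
           effect_profile = vals[["effect_profile"]],
           n_sample = as.integer(vals["n_sample"]),
           pool_size = as.integer(vals["pool_size"]))
}
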