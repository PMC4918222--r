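#' Monte-Carlo experiment configuration
#'
#' Describes one cell of a rejection-rate study: a benchmark scenario, the
#' tests to run, the number of replications R, the permutation count B, the
#' nominal level alpha and the master seed. Under \code{null = TRUE} all
#' effect vectors are forced to zero and the estimated rate is an empirical
#' type-I error; otherwise it is a power.
#'
#' @param scenario_id,K,rho,effect_profile,n_sample,pool_size passed to
#'   [scenario()].
#' @param tests subset of \code{c("MIT", "aMIT", "Score")}.
#' @param null simulate under the no-association null?
#' @param R number of replications (>= 1).
#' @param B permutations per replication for MIT/aMIT (>= 1).
#' @param alpha nominal significance level in (0, 1).
#' @param seed master seed; replication seeds and the pool seed are derived
#'   from it, so results are independent of execution order.
#' @param redraw_pool if TRUE a fresh pool (new MAFs and class positions) is
#'   drawn for every replication instead of one fixed pool per experiment.
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(scenario_id, K = 3, rho = 0,
                              tests = c("MIT", "aMIT", "Score"),
                              null = FALSE, effect_profile = "default",
                              R = 200L, B = 500L, alpha = 0.05,
                              n_sample = 1000L, pool_size = 200000L,
                              seed = 1L, redraw_pool = FALSE) {
  tests <- match.arg(tests, c("MIT", "aMIT", "Score"), several.ok = TRUE)
  R <- as.integer(R); B <- as.integer(B)
  if (R < 1L) stop("R must be >= 1")
  if (B < 1L) stop("B must be >= 1")
  # alpha = 1 is admitted as a degenerate threshold (every p <= 1 rejects)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(scenario = scenario(scenario_id, K = K, rho = rho,
                                     effect_profile = effect_profile,
                                     n_sample = n_sample, pool_size = pool_size),
                 tests = tests, null = null, R = R, B = B, alpha = alpha,
                 seed = as.integer(seed), redraw_pool = isTRUE(redraw_pool)),
            class = "experiment_config")
}

## Statistics and p-values of the requested tests on one dataset, sharing
## one permutation stream between MIT and aMIT.
.replicate_pvalues <- function(geno, trait, tests, B) {
  p <- setNames(rep(NA_real_, length(tests)), tests)
  stat <- p
  mi <- intersect(tests, c("MIT", "aMIT"))
  if (length(mi)) {
    res <- mi_region_test(geno, trait, tests = mi, B = B)
    for (s in mi) {
      p[s] <- res[[s]]$p_value
      stat[s] <- res[[s]]$statistic
    }
  }
  if ("Score" %in% tests) {
    sc <- score_statistic(geno, trait)
    p["Score"] <- sc$p_value
    stat["Score"] <- sc$statistic
  }
  list(p = p, stat = stat)
}

#' Run a rejection-rate experiment
#'
#' For r = 1..R: draw a sample of n individuals from the scenario pool,
#' compute each requested test's p-value (permutation with B shuffles for
#' MIT/aMIT, chi-square tail for Score) and reject when p <= alpha. Returns
#' per-test empirical rejection rates with binomial standard errors
#' sqrt(rate (1 - rate) / R). Fully determined by the master seed.
#'
#' @param config an [experiment_config()].
#' @param progress emit a structured log line per replication
#'   (\code{r=<r> test=<t> statistic=<T> p=<p>}) to stderr?
#' @return object of class \code{rejection_rates}: a data.frame with columns
#'   test, rate, se, R, B, alpha, scenario, K, rho, null, effect_profile,
#'   seed; the R x tests matrix of p-values is attached as attribute
#'   \code{"pvalues"}.
#' @export
run_experiment <- function(config, progress = FALSE) {
  sc <- config$scenario
  seeds <- .child_seeds(config$seed, config$R + 1L)
  pool <- if (config$redraw_pool) NULL
          else simulate_pool(sc, seeds[1], null = config$null)
  pv <- matrix(NA_real_, config$R, length(config$tests),
               dimnames = list(NULL, config$tests))
  for (r in seq_len(config$R)) {
    rs <- seeds[r + 1L]
    dat <- if (config$redraw_pool) generate_dataset(sc, rs, null = config$null)
           else sample_from_pool(pool, seed = rs)
    rep_res <- .replicate_pvalues(dat$geno, dat$trait, config$tests, config$B)
    pv[r, ] <- rep_res$p
    if (progress)
      for (tst in config$tests)
        message(sprintf("r=%d test=%s statistic=%.6g p=%.6g",
                        r, tst, rep_res$stat[tst], rep_res$p[tst]))
  }
  rate <- colMeans(pv <= config$alpha)
  out <- data.frame(test = config$tests,
                    rate = unname(rate),
                    se = unname(sqrt(rate * (1 - rate) / config$R)),
                    R = config$R, B = config$B, alpha = config$alpha,
                    scenario = sc$scenario_id, K = sc$K, rho = sc$rho,
                    null = config$null, effect_profile = sc$effect_profile,
                    seed = config$seed,
                    row.names = NULL)
  attr(out, "pvalues") <- pv
  class(out) <- c("rejection_rates", "data.frame")
  out
}

#' Tabulate rejection-rate results
#'
#' Combines results into a long table and a wide pivot with one row per
#' (scenario, effect profile, rho) and one column per test, the layout of the
#' benchmark type-I-error and power tables.
#'
#' @param results list of \code{rejection_rates} objects (or a single one).
#' @return list with elements \code{long} and \code{wide} (data.frames).
#' @export
tabulate_results <- function(results) {
  if (inherits(results, "rejection_rates")) results <- list(results)
  if (!length(results)) {
    long <- data.frame(test = character(), rate = numeric(), se = numeric(),
                       R = integer(), B = integer(), alpha = numeric(),
                       scenario = integer(), K = integer(), rho = numeric(),
                       null = logical(), effect_profile = character(),
                       seed = integer())
    return(list(long = long,
                wide = data.frame(scenario = integer(), K = integer(),
                                  effect_profile = character(), rho = numeric())))
  }
  long <- do.call(rbind, lapply(results, as.data.frame))
  if (length(unique(long$alpha)) > 1L)
    stop("results mix different nominal levels alpha")
  key <- interaction(long$scenario, long$K, long$effect_profile, long$rho,
                     long$null, long$test, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (scenario, K, effect_profile, rho, null, test) cells")
  cells <- unique(long[, c("scenario", "K", "effect_profile", "rho", "null")])
  wide <- cells
  for (tst in unique(long$test)) {
    wide[[tst]] <- vapply(seq_len(nrow(cells)), function(i) {
      sel <- long$test == tst &
        long$scenario == cells$scenario[i] & long$K == cells$K[i] &
        long$effect_profile == cells$effect_profile[i] &
        long$rho == cells$rho[i] & long$null == cells$null[i]
      if (any(sel)) long$rate[sel][1] else NA_real_
    }, numeric(1))
  }
  rownames(wide) <- NULL
  list(long = long, wide = wide)
}
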