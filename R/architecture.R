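#' Closed-form expected recurrence of gene hits
#'
#' For `n` gene hits drawn uniformly with replacement from a pool of `p`
#' equally likely disease genes, gives the expected number of distinct genes
#' hit, the expected number hit at least twice (recurrent), and the expected
#' recurrence rate. With \eqn{P_0 = (1 - 1/p)^n} (a gene never hit) and
#' \eqn{P_1 = (n/p)(1 - 1/p)^{n-1}} (hit exactly once):
#' \eqn{E[\mathrm{distinct}] = p(1 - P_0)} and
#' \eqn{E[\mathrm{recurrent}] = p(1 - P_0 - P_1)}.
#'
#' This is the analytic counterpart of [simulate_recurrence()]; the
#' simulation converges to it as replicates grow.
#'
#' @param p Pool size: number of equally likely monogenic disease genes.
#' @param n Number of gene hits sampled with replacement.
#' @param r_definition How the recurrence rate is normalised:
#'   `"recurrent_over_distinct"` (recurrent genes / distinct genes hit, the
#'   statistic a sequencing study observes) or `"recurrent_over_draws"`
#'   (recurrent genes / hits).
#' @return A tibble with columns `p`, `n`, `e_distinct`, `e_recurrent`, `r`.
#' @examples
#' expected_recurrence(p = 625, n = 123)
#' @export
expected_recurrence <- function(p, n,
                                r_definition = c("recurrent_over_distinct",
                                                 "recurrent_over_draws")) {
  r_definition <- match.arg(r_definition)
  assert_that(all(p >= 1) && all(p == floor(p)), "`p` must be integers >= 1")
  assert_that(all(n >= 1) && all(n == floor(n)), "`n` must be integers >= 1")
  grid <- tibble(p = as.numeric(p), n = as.numeric(n))
  p0 <- (1 - 1 / grid$p)^grid$n
  p1 <- (grid$n / grid$p) * (1 - 1 / grid$p)^(grid$n - 1)
  e_dist <- grid$p * (1 - p0)
  e_rec <- pmax(grid$p * (1 - p0 - p1), 0)
  r <- switch(r_definition,
    recurrent_over_distinct = ifelse(e_dist > 0, e_rec / e_dist, 0),
    recurrent_over_draws = e_rec / grid$n
  )
  tibble(p = grid$p, n = grid$n, e_distinct = e_dist, e_recurrent = e_rec, r = r)
}

# one vectorised batch of recurrence replicates: r per replicate
# (all `reps` replicates share one tabulate pass keyed by replicate * p)
sim_r_reps <- function(p, n, reps) {
  p <- as.integer(p); n <- as.integer(n); reps <- as.integer(reps)
  draws <- sample.int(p, n * reps, replace = TRUE)
  key <- (rep(seq_len(reps), each = n) - 1L) * p + draws
  tab <- tabulate(key, nbins = reps * p)
  nz <- which(tab > 0L)
  rec <- which(tab > 1L)
  d_per <- tabulate((nz - 1L) %/% p + 1L, nbins = reps)
  r_per <- tabulate((rec - 1L) %/% p + 1L, nbins = reps)
  list(distinct = d_per, recurrent = r_per)
}

#' Monte Carlo expected recurrence rate
#'
#' Simulates `reps` studies, each drawing `n_draws` gene hits uniformly with
#' replacement from a pool of `p` genes, and records the recurrence rate of
#' each; returns the mean and its Monte Carlo standard error.
#'
#' @param p Pool size (single positive integer).
#' @param n_draws Gene hits per replicate.
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @inheritParams expected_recurrence
#' @return A tibble with columns `p`, `n`, `reps`, `r_mean`, `r_se` (the
#'   per-replicate ratio, averaged - the estimator a grid search uses), and
#'   `r_pooled`, `r_pooled_se` (ratio of the replicate-mean recurrent and
#'   distinct counts, with a delta-method standard error). `r_pooled` is
#'   the statistic the closed form of [expected_recurrence()] describes;
#'   `r_mean` carries a small Jensen bias of order 1/p above it because
#'   the ratio is averaged across finite replicates.
#' @examples
#' simulate_recurrence(p = 625, n_draws = 123, reps = 200, seed = 1)
#' @export
simulate_recurrence <- function(p, n_draws, reps = 1000, seed = 1,
                                r_definition = c("recurrent_over_distinct",
                                                 "recurrent_over_draws")) {
  r_definition <- match.arg(r_definition)
  assert_count(p, "p"); assert_count(n_draws, "n_draws"); assert_count(reps, "reps")
  sim <- with_seed(seed, sim_r_reps(p, n_draws, reps))
  denom <- switch(r_definition,
    recurrent_over_distinct = sim$distinct,
    recurrent_over_draws = rep(n_draws, reps))
  r <- ifelse(denom > 0, sim$recurrent / denom, 0)
  # ratio of means, with a delta-method SE
  md <- mean(denom); mr <- mean(sim$recurrent)
  r_pooled <- mr / md
  vr <- var(sim$recurrent); vd <- var(denom)
  cvd <- if (vd > 0) cov(sim$recurrent, denom) else 0
  r_pooled_se <- sqrt(max(vr - 2 * r_pooled * cvd + r_pooled^2 * vd, 0) /
                        reps) / md
  tibble(p = p, n = n_draws, reps = reps,
         r_mean = mean(r), r_se = sd(r) / sqrt(reps),
         r_pooled = r_pooled, r_pooled_se = r_pooled_se)
}

#' Estimate the monogenic gene-pool size from an observed recurrence rate
#'
#' Grid search for the pool size whose Monte Carlo expected recurrence rate
#' is closest to the observed rate `r_obs`. For each candidate pool size in
#' `grid`, `reps` replicates of `n_draws` uniform-with-replacement gene hits
#' are simulated and the replicate-mean recurrence rate is compared with
#' `r_obs`; the estimate is the grid value minimising the absolute
#' difference (smallest pool on ties).
#'
#' @param r_obs Observed recurrence rate among prioritized genes, in [0, 1].
#' @param n_draws Number of gene hits behind the observation.
#' @param grid Candidate pool sizes (default `1:1000`).
#' @param reps Monte Carlo replicates per grid value (default 1000).
#' @param seed Integer seed.
#' @inheritParams expected_recurrence
#' @return A `pool_estimate` object: list with `p_hat`, `r_obs`, `n_draws`,
#'   `at_boundary` (estimate sits at a grid end), and `objective_curve`
#'   (tibble of `p`, `r_mean`, `objective`).
#' @examples
#' est <- estimate_pool_size(r_obs = 0.3, n_draws = 100,
#'                           grid = seq(50, 400, by = 5), reps = 200, seed = 1)
#' est$p_hat
#' @export
estimate_pool_size <- function(r_obs, n_draws, grid = 1:1000, reps = 1000,
                               seed = 1,
                               r_definition = c("recurrent_over_distinct",
                                                "recurrent_over_draws")) {
  r_definition <- match.arg(r_definition)
  assert_scalar_num(r_obs, "r_obs", 0, 1)
  assert_count(n_draws, "n_draws")
  assert_that(length(grid) >= 1 && all(grid >= 1) && all(grid == floor(grid)),
              "`grid` must contain positive integers")
  grid <- sort(unique(as.integer(grid)))
  r_mean <- with_seed(seed, vapply(grid, function(p) {
    sim <- sim_r_reps(p, n_draws, reps)
    r <- switch(r_definition,
      recurrent_over_distinct = ifelse(sim$distinct > 0,
                                       sim$recurrent / sim$distinct, 0),
      recurrent_over_draws = sim$recurrent / n_draws)
    mean(r)
  }, numeric(1)))
  objective <- abs(r_mean - r_obs)
  i_hat <- which.min(objective) # first minimum = smallest p on ties
  at_boundary <- i_hat == 1L || i_hat == length(grid)
  if (at_boundary)
    rlang::warn("pool-size estimate sits at a grid boundary; widen `grid`")
  structure(
    list(p_hat = grid[i_hat], r_obs = r_obs, n_draws = n_draws,
         reps = reps, r_definition = r_definition, at_boundary = at_boundary,
         objective_curve = tibble(p = grid, r_mean = r_mean,
                                  objective = objective)),
    class = "pool_estimate")
}

#' @export
print.pool_estimate <- function(x, ...) {
  cat("Gene-pool size estimate (recurrence Monte Carlo)\n")
  cat(sprintf("  observed recurrence r_obs = %.4g over n = %d gene hits\n",
              x$r_obs, x$n_draws))
  cat(sprintf("  p_hat = %d genes (grid %d..%d, %d reps, r = %s)\n",
              x$p_hat, min(x$objective_curve$p), max(x$objective_curve$p),
              x$reps, x$r_definition))
  if (x$at_boundary) cat("  WARNING: estimate at grid boundary\n")
  invisible(x)
}

#' Adjust a pool-size estimate for the prioritization false-discovery rate
#'
#' Re-estimates the pool size after accounting for a fraction `fdr` of the
#' observed gene hits being false positives, under one of two placement
#' models. Under `"unique_background"` the false hits land on distinct
#' background genes and never recur, so the expected observed rate for pool
#' `p` is \eqn{E[\mathrm{rec}](p, n(1-f)) / (E[\mathrm{dist}](p, n(1-f)) + nf)};
#' the estimate is refit against `r_obs` with this corrected expectation.
#' Under `"within_pool"` false hits are drawn from the same pool as true
#' hits and the estimate is unchanged by construction.
#'
#' @param estimate A [estimate_pool_size()] result.
#' @param fdr Fraction of observed hits that are false positives, in [0, 1).
#' @param model `"unique_background"` or `"within_pool"`.
#' @inheritParams estimate_pool_size
#' @return A `pool_estimate` with extra fields `fdr`, `fp_model`, and
#'   `relative_change` (adjusted / original p_hat).
#' @export
adjust_for_fdr <- function(estimate, fdr,
                           model = c("unique_background", "within_pool"),
                           reps = NULL, seed = 1) {
  assert_that(inherits(estimate, "pool_estimate"),
              "`estimate` must come from estimate_pool_size()")
  assert_scalar_num(fdr, "fdr", 0, 1, strict_upper = TRUE)
  model <- match.arg(model)
  reps <- reps %||% estimate$reps
  if (fdr == 0 || model == "within_pool") {
    adj <- estimate
  } else {
    n <- estimate$n_draws
    n_true <- max(1L, as.integer(round(n * (1 - fdr))))
    n_false <- n - n_true
    grid <- estimate$objective_curve$p
    r_mean <- with_seed(seed, vapply(grid, function(p) {
      sim <- sim_r_reps(p, n_true, reps)
      denom <- sim$distinct + n_false
      mean(ifelse(denom > 0, sim$recurrent / denom, 0))
    }, numeric(1)))
    objective <- abs(r_mean - estimate$r_obs)
    i_hat <- which.min(objective)
    adj <- estimate
    adj$p_hat <- grid[i_hat]
    adj$at_boundary <- i_hat == 1L || i_hat == length(grid)
    adj$objective_curve <- tibble(p = grid, r_mean = r_mean,
                                  objective = objective)
  }
  adj$fdr <- fdr
  adj$fp_model <- model
  adj$relative_change <- adj$p_hat / estimate$p_hat
  adj
}

#' Bracket the expected recurrence rate under false-positive contamination
#'
#' Given pool size `p`, `n` observed gene hits of which a fraction `fdr` are
#' false positives, evaluates the closed-form expected recurrence rate under
#' the two extreme placement assumptions: false hits landing on unique
#' background genes that never recur (`r_low`) versus false hits drawn from
#' the same pool as true hits (`r_high`). The truth lies between.
#'
#' @inheritParams expected_recurrence
#' @param fdr False-positive fraction of hits, in [0, 1).
#' @return A tibble with columns `p`, `n`, `fdr`, `r_low`, `r_high`.
#' @examples
#' fp_recurrence_bounds(p = 625, n = 221, fdr = 0.30)
#' @export
fp_recurrence_bounds <- function(p, n, fdr) {
  assert_count(p, "p"); assert_count(n, "n")
  assert_scalar_num(fdr, "fdr", 0, 1, strict_upper = TRUE)
  r_high <- expected_recurrence(p, n)$r
  if (fdr == 0) {
    r_low <- r_high
  } else {
    n_true <- n * (1 - fdr)
    n_false <- n * fdr
    p0 <- (1 - 1 / p)^n_true
    p1 <- (n_true / p) * (1 - 1 / p)^(n_true - 1)
    e_dist <- p * (1 - p0)
    e_rec <- p * (1 - p0 - p1)
    r_low <- e_rec / (e_dist + n_false)
  }
  tibble(p = p, n = n, fdr = fdr, r_low = r_low, r_high = r_high)
}

# mean fraction of the pool hit >= k times in a cohort of n cases
coverage_at_n <- function(n, pool_size, discovery_rate, k, reps) {
  m <- rbinom(reps, n, discovery_rate)
  total <- sum(m)
  if (total == 0) return(0)
  g <- sample.int(pool_size, total, replace = TRUE)
  key <- (rep(seq_len(reps), times = m) - 1L) * pool_size + g
  tab <- tabulate(key, nbins = reps * pool_size)
  rec <- which(tab >= k)
  mean(tabulate((rec - 1L) %/% pool_size + 1L, nbins = reps)) / pool_size
}

#' Project the cohort size required to observe recurrent gene hits
#'
#' Simulates cohorts in which each case independently carries a discoverable
#' monogenic cause with probability `discovery_rate`, with the causal gene
#' uniform over a pool of `pool_size` genes, and finds the minimal cohort
#' size at which the mean fraction of pool genes observed in at least
#' `recurrence_k` cases reaches `coverage_target`. The search is bisection
#' followed by a linear scan of +/- 5 around the bisection answer to guard
#' against Monte Carlo noise.
#'
#' @param pool_size Number of equally likely disease genes.
#' @param discovery_rate Per-case probability of carrying a discoverable
#'   cause, in (0, 1].
#' @param coverage_target Required mean fraction of the pool seen
#'   recurrently (default 0.5).
#' @param recurrence_k Minimum number of cases per gene to call it
#'   recurrent (default 2).
#' @param reps Monte Carlo replicates per evaluated cohort size.
#' @param seed Integer seed.
#' @param n_max Upper bound for the search; the search fails loudly if the
#'   target is not reached by `n_max`.
#' @return A `cohort_projection` object: list with `n_required`, the input
#'   parameters, and `curve` (tibble of evaluated `n` and mean coverage).
#' @examples
#' proj <- project_cohort_size(pool_size = 100, discovery_rate = 0.5,
#'                             reps = 300, seed = 1)
#' proj$n_required
#' @export
project_cohort_size <- function(pool_size, discovery_rate,
                                coverage_target = 0.5, recurrence_k = 2,
                                reps = 1000, seed = 1, n_max = NULL) {
  assert_count(pool_size, "pool_size")
  assert_scalar_num(discovery_rate, "discovery_rate", 0, 1, strict_lower = TRUE)
  assert_scalar_num(coverage_target, "coverage_target", 0, 1,
                    strict_lower = TRUE)
  assert_count(recurrence_k, "recurrence_k")
  if (coverage_target >= 1)
    rlang::abort("`coverage_target` >= 1 is unreachable for a finite pool")
  n_max <- n_max %||% ceiling(50 * pool_size / discovery_rate)

  evals <- new.env(parent = emptyenv())
  eval_cov <- function(n) {
    key <- as.character(n)
    if (!is.null(evals[[key]])) return(evals[[key]])
    cv <- with_seed(child_seed(seed, n),
                    coverage_at_n(n, pool_size, discovery_rate,
                                  recurrence_k, reps))
    evals[[key]] <- cv
    cv
  }

  # grow upper bracket
  hi <- max(16L, as.integer(ceiling(pool_size / discovery_rate)))
  while (eval_cov(hi) < coverage_target) {
    hi <- hi * 2L
    if (hi > n_max)
      rlang::abort(sprintf(
        "coverage target %.2f not reached by n = %d cases", coverage_target,
        n_max))
  }
  lo <- 1L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (eval_cov(mid) >= coverage_target) hi <- mid else lo <- mid
  }
  # linear scan around the bisection answer
  scan <- seq.int(max(1L, hi - 5L), hi + 5L)
  ok <- vapply(scan, function(n) eval_cov(n) >= coverage_target, logical(1))
  n_required <- if (any(ok)) scan[which(ok)[1]] else hi

  ns <- sort(as.integer(ls(evals)))
  curve <- tibble(n = ns,
                  coverage = vapply(as.character(ns),
                                    function(k) evals[[k]], numeric(1)))
  structure(
    list(n_required = n_required, pool_size = pool_size,
         discovery_rate = discovery_rate, coverage_target = coverage_target,
         recurrence_k = recurrence_k, reps = reps, curve = curve),
    class = "cohort_projection")
}

#' @export
print.cohort_projection <- function(x, ...) {
  cat("Cohort-size projection for recurrent gene discovery\n")
  cat(sprintf(
    "  pool %d genes, discovery rate %.2f, target %.2f of pool seen >= %d times\n",
    x$pool_size, x$discovery_rate, x$coverage_target, x$recurrence_k))
  cat(sprintf("  minimal cohort size: n = %d cases\n", x$n_required))
  invisible(x)
}
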