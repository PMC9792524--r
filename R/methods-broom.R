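#' Tidy a pool-size estimate
#'
#' Returns the objective curve: one row per candidate pool size with the
#' Monte Carlo mean recurrence rate and the objective `|r_mean - r_obs|`.
#'
#' @param x A [estimate_pool_size()] result.
#' @param ... Unused.
#' @return A tibble with columns `p`, `r_mean`, `objective`.
#' @export
tidy.pool_estimate <- function(x, ...) x$objective_curve

#' One-row summary of a pool-size estimate
#'
#' @param x A [estimate_pool_size()] result.
#' @param ... Unused.
#' @return A tibble with `p_hat`, `r_obs`, `n_draws`, `reps`,
#'   `r_definition`, `at_boundary`.
#' @export
glance.pool_estimate <- function(x, ...) {
  tibble(p_hat = x$p_hat, r_obs = x$r_obs, n_draws = x$n_draws,
         reps = x$reps, r_definition = x$r_definition,
         at_boundary = x$at_boundary)
}

#' Tidy a cohort-size projection
#'
#' @param x A [project_cohort_size()] result.
#' @param ... Unused.
#' @return The evaluated power curve: tibble of `n`, `coverage`.
#' @export
tidy.cohort_projection <- function(x, ...) x$curve

#' One-row summary of a cohort-size projection
#'
#' @param x A [project_cohort_size()] result.
#' @param ... Unused.
#' @return A tibble with `n_required`, `pool_size`, `discovery_rate`,
#'   `coverage_target`, `recurrence_k`, `reps`.
#' @export
glance.cohort_projection <- function(x, ...) {
  tibble(n_required = x$n_required, pool_size = x$pool_size,
         discovery_rate = x$discovery_rate,
         coverage_target = x$coverage_target,
         recurrence_k = x$recurrence_k, reps = x$reps)
}

#' Tidy a prioritization result
#'
#' @param x A `prioritization_result`.
#' @param ... Unused.
#' @return The audit trail: tibble of `finding_id`, `dropped_by` (`NA` for
#'   surviving findings).
#' @export
tidy.prioritization_result <- function(x, ...) x$audit

#' One-row summary of a prioritization result
#'
#' @param x A `prioritization_result`.
#' @param ... Unused.
#' @return A tibble with `stage`, `n_input`, `n_surviving`, `n_dropped`,
#'   `n_genes`.
#' @export
glance.prioritization_result <- function(x, ...) {
  tibble(stage = x$stage, n_input = nrow(x$audit),
         n_surviving = nrow(x$surviving),
         n_dropped = sum(!is.na(x$audit$dropped_by)),
         n_genes = dplyr::n_distinct(x$surviving$gene_id))
}

#' Tidy an ROH length-mixture fit
#'
#' @param x An [fit_length_mixture()] result.
#' @param ... Unused.
#' @return The components table: `class`, `mean_log`, `sd_log`, `weight`.
#' @export
tidy.roh_mixture <- function(x, ...) x$components

#' One-row summary of an ROH length-mixture fit
#'
#' @param x An [fit_length_mixture()] result.
#' @param ... Unused.
#' @return A tibble with `k`, `n`, `loglik`, `iterations`.
#' @export
glance.roh_mixture <- function(x, ...) {
  tibble(k = x$k, n = x$n, loglik = x$loglik,
         iterations = length(x$loglik_trace))
}
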