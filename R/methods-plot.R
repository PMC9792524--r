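#' Plot the pool-size objective curve
#'
#' Objective `|mean r - r_obs|` against candidate pool size, with the
#' estimate marked.
#'
#' @param object A [estimate_pool_size()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pool_estimate <- function(object, ...) {
  ggplot(object$objective_curve, aes(x = .data$p, y = .data$objective)) +
    geom_line(colour = "grey40") +
    geom_vline(xintercept = object$p_hat, linetype = 2, colour = "firebrick") +
    labs(x = "candidate pool size p (genes)",
         y = expression("|" * bar(r) - r[obs] * "|"),
         title = sprintf("Gene-pool size estimate: p = %d", object$p_hat)) +
    theme_minimal()
}

#' Plot a cohort-size power curve
#'
#' Mean fraction of the gene pool observed recurrently against cohort
#' size, with the coverage target and the minimal sufficient cohort size
#' marked.
#'
#' @param object A [project_cohort_size()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_projection <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$n, y = .data$coverage)) +
    geom_line(colour = "grey40") + geom_point(size = 0.8) +
    geom_hline(yintercept = object$coverage_target, linetype = 3) +
    geom_vline(xintercept = object$n_required, linetype = 2,
               colour = "firebrick") +
    labs(x = "cohort size (cases)",
         y = sprintf("fraction of pool seen in >= %d cases",
                     object$recurrence_k),
         title = sprintf("Required cohort size: n = %d at discovery rate %.2f",
                         object$n_required, object$discovery_rate)) +
    theme_minimal()
}

#' Plot a piRNA read-length histogram
#'
#' Spike-normalized read counts by length, with the mature/immature cutoff
#' marked.
#'
#' @param object A [pirna_histogram()].
#' @param cutoff Mature-length cutoff drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pirna_histogram <- function(object, cutoff = 32, ...) {
  d <- spike_normalize(object)
  ggplot(d, aes(x = .data$length, y = .data$count_norm)) +
    geom_col(fill = "steelblue") +
    geom_vline(xintercept = cutoff - 0.5, linetype = 2) +
    labs(x = "read length (nt)", y = "reads per spike-in read",
         title = "piRNA length distribution") +
    theme_minimal()
}

#' Plot a component gene-count profile
#'
#' Counts of query-set genes among each component's top-loading genes.
#'
#' @param object A [profile_counts()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_profile <- function(object, ...) {
  d <- as_tibble(object)
  d$component <- factor(d$component, levels = unique(d$component))
  ggplot(d, aes(x = .data$component, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = "component", y = "genes in top-loading set",
         title = "Component gene-count profile") +
    theme_minimal()
}
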