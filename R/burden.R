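#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test on a 2x2 table of counts (rows = group, columns
#' = carrier / non-carrier). The two-sided p-value follows the
#' minimum-likelihood convention: the sum of the point probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table.
#'
#' @param table A 2x2 numeric matrix of non-negative counts, or a length-4
#'   vector `c(a, b, c, d)` filling the table by row.
#' @param alternative `"two_sided"`, `"greater"` (first row enriched for the
#'   first column), or `"less"`.
#' @return A tibble with columns `p`, `odds_ratio`, `alternative`. The odds
#'   ratio is the sample odds ratio `ad/bc`, `Inf` or 0 with empty cells,
#'   `NaN` when undefined.
#' @examples
#' fisher_exact(matrix(c(55, 17, 127, 725), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  assert_that(is.matrix(table) && all(dim(table) == 2) &&
                all(table >= 0) && all(table == floor(table)),
              "`table` must be a 2x2 matrix of non-negative integer counts")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  if (sum(table) == 0) {
    rlang::warn("all-zero contingency table; p = 1")
    return(tibble(p = 1, odds_ratio = NaN, alternative = alternative))
  }
  m1 <- a + b      # row-1 total
  k <- a + cc      # column-1 total
  m2 <- cc + d
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- switch(alternative,
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    # relative tolerance guards floating-point ties at the observed mass
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)])
  )
  or <- if (b == 0 && cc == 0) NaN
        else if (b == 0 || cc == 0) Inf
        else if (a == 0 || d == 0) (a * d) / (b * cc)  # 0
        else (a * d) / (b * cc)
  # clamp to the open-zero interval: an exact tail is never exactly zero
  p <- min(max(p, .Machine$double.xmin), 1)
  tibble(p = p, odds_ratio = or, alternative = alternative)
}

#' Per-gene carrier-burden test
#'
#' Compares the proportion of carriers of prioritized variants in a gene
#' between cases and controls with Fisher's exact test, and applies a
#' significance threshold (see [two_stage_threshold()]). Burden testing uses
#' single-variant genotype calls only; compound-heterozygous carriers must
#' be excluded upstream.
#'
#' @param gene_id Gene identifier (carried through to the result).
#' @param case_carriers,n_cases Carrier count and cohort size among cases.
#' @param control_carriers,n_controls Same for controls.
#' @param threshold Significance threshold on the two-sided p (strict `<`);
#'   default is the exome-wide two-stage threshold 2.5e-6.
#' @param haldane Apply the Haldane +0.5 continuity correction to the odds
#'   ratio (default `FALSE`, plain sample odds ratio with `Inf` for empty
#'   cells).
#' @return A `burden_result` tibble (one row) with the 2x2 counts, odds
#'   ratio, two- and one-sided p-values and `significant_two_stage`.
#' @examples
#' carrier_burden_test("PNLDC1", 3, 2072, 0, 11587)
#' @export
carrier_burden_test <- function(gene_id, case_carriers, n_cases,
                                control_carriers, n_controls,
                                threshold = two_stage_threshold(),
                                haldane = FALSE) {
  assert_count(case_carriers, "case_carriers", min = 0L)
  assert_count(control_carriers, "control_carriers", min = 0L)
  assert_that(case_carriers <= n_cases && control_carriers <= n_controls,
              "carrier counts cannot exceed cohort sizes")
  a <- case_carriers; b <- n_cases - case_carriers
  cc <- control_carriers; d <- n_controls - control_carriers
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
  p2 <- fisher_exact(tab, "two_sided")$p
  p1 <- fisher_exact(tab, "greater")$p
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else fisher_exact(tab, "two_sided")$odds_ratio
  out <- tibble(gene_id = gene_id,
                case_carriers = a, n_cases = n_cases,
                control_carriers = cc, n_controls = n_controls,
                odds_ratio = or, p_two_sided = p2, p_one_sided = p1,
                significant_two_stage = p2 < threshold)
  class(out) <- c("burden_result", class(out))
  out
}

#' Two-stage Bonferroni significance threshold
#'
#' In a two-stage burden design (gene discovery in a first cohort,
#' association testing in the combined cohorts), p-values must be corrected
#' for the number of genes effectively screened in the first stage. The
#' conservative choice is exome-wide: 20,000 single-gene tests, giving
#' `0.05 / 20000 = 2.5e-6`.
#'
#' @param n_first_stage_genes Number of genes screened in the first stage
#'   (default 20000).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-gene significance threshold `alpha / n_first_stage_genes`.
#' @export
two_stage_threshold <- function(n_first_stage_genes = 20000, alpha = 0.05) {
  assert_count(n_first_stage_genes, "n_first_stage_genes")
  assert_scalar_num(alpha, "alpha", 0, 1, strict_lower = TRUE)
  alpha / n_first_stage_genes
}

#' One-tailed binomial test for depleted counts
#'
#' Exact lower-tail binomial probability of observing at most `k_observed`
#' events in `n_trials` at rate `rate_expected`; used e.g. to ask whether a
#' control cohort shows fewer novel knockout genotypes than expected.
#'
#' @param k_observed Observed event count.
#' @param n_trials Number of trials.
#' @param rate_expected Expected per-trial event probability.
#' @return The exact p-value `P(X <= k_observed)`.
#' @examples
#' binomial_depletion_test(0, 10, 0.5)  # 2^-10
#' @export
binomial_depletion_test <- function(k_observed, n_trials, rate_expected) {
  assert_count(k_observed, "k_observed", min = 0L)
  assert_count(n_trials, "n_trials")
  assert_scalar_num(rate_expected, "rate_expected", 0, 1)
  assert_that(k_observed <= n_trials, "`k_observed` cannot exceed `n_trials`")
  pbinom(k_observed, n_trials, rate_expected)
}

#' Burden tests across a gene table
#'
#' Convenience wrapper running [carrier_burden_test()] over a tidy table of
#' per-gene carrier counts.
#'
#' @param counts A data frame with columns `gene_id`, `case_carriers`,
#'   `control_carriers`.
#' @param n_cases,n_controls Cohort sizes shared by all genes.
#' @inheritParams carrier_burden_test
#' @return A `burden_result` tibble with one row per gene, sorted by
#'   `p_two_sided`.
#' @export
burden_scan <- function(counts, n_cases, n_controls,
                        threshold = two_stage_threshold()) {
  assert_that(all(c("gene_id", "case_carriers", "control_carriers") %in%
                    names(counts)),
              "`counts` needs gene_id, case_carriers, control_carriers")
  out <- purrr::pmap(
    list(counts$gene_id, counts$case_carriers, counts$control_carriers),
    function(g, a, c_) carrier_burden_test(g, a, n_cases, c_, n_controls,
                                           threshold = threshold)) |>
    purrr::list_rbind()
  out <- dplyr::arrange(out, .data$p_two_sided)
  class(out) <- c("burden_result", class(out))
  out
}
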