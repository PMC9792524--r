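#' Spike-in normalization of a piRNA histogram
#'
#' Divides every length count by the spike-in read count, yielding
#' comparable per-spike read abundances across libraries. The length
#' support is unchanged and all count ratios are preserved; the mature
#' fraction is invariant under this normalization.
#'
#' @param hist A [pirna_histogram()].
#' @return A tibble with columns `length`, `count`, `count_norm`.
#' @export
spike_normalize <- function(hist) {
  assert_that(inherits(hist, "pirna_histogram"),
              "`hist` must be a pirna_histogram")
  spike <- attr(hist, "spike_in_count")
  assert_that(is.numeric(spike) && spike > 0,
              "spike-in count must be positive")
  out <- as_tibble(hist)
  out$count_norm <- out$count / spike
  out
}

#' Mature piRNA fraction of a length histogram
#'
#' Fraction of reads strictly shorter than `cutoff` nucleotides (mature
#' piRNAs are ~26-31 nt; the precursor tail runs to 45 nt).
#'
#' @param hist A [pirna_histogram()] or a data frame with `length` and
#'   `count`.
#' @param cutoff Strict upper length bound for "mature" (default 32, i.e.
#'   lengths < 32 nt count as mature).
#' @return The mature fraction in [0, 1]; `NA` (with a warning) for an
#'   empty histogram.
#' @examples
#' h <- pirna_histogram(c(`28` = 50, `30` = 30, `34` = 20), 100)
#' mature_fraction(h)  # 0.8
#' @export
mature_fraction <- function(hist, cutoff = 32) {
  assert_that(is.data.frame(hist) &&
                all(c("length", "count") %in% names(hist)),
              "`hist` needs columns length and count")
  total <- sum(hist$count)
  if (total == 0) {
    rlang::warn("empty histogram; mature fraction undefined")
    return(NA_real_)
  }
  sum(hist$count[hist$length < cutoff]) / total
}

#' Compare piRNA maturity between a case and its matched control
#'
#' Computes the mature (< `cutoff` nt) read fraction in each library, the
#' control/case fold change, and a one-sided hypergeometric
#' (Fisher-exact-tail) p-value for the case having a lower mature fraction,
#' on the raw 2x2 read counts (mature/immature x case/control). Raw counts
#' are used because the exact test requires integer counts; spike-in
#' normalization only rescales a library and cannot change either fraction.
#'
#' @param case_hist,control_hist [pirna_histogram()] objects.
#' @param cutoff Strict mature-length bound (default 32).
#' @return A one-row `maturity_result` tibble: `mature_fraction_case`,
#'   `mature_fraction_control`, `fold_change` (control/case),
#'   `p_hypergeometric`.
#' @export
compare_maturity <- function(case_hist, control_hist, cutoff = 32) {
  for (h in list(case_hist, control_hist))
    assert_that(sum(h$count) > 0, "both histograms must contain reads")
  f_case <- mature_fraction(case_hist, cutoff)
  f_ctrl <- mature_fraction(control_hist, cutoff)
  m_case <- sum(case_hist$count[case_hist$length < cutoff])
  i_case <- sum(case_hist$count) - m_case
  m_ctrl <- sum(control_hist$count[control_hist$length < cutoff])
  i_ctrl <- sum(control_hist$count) - m_ctrl
  tab <- matrix(c(m_case, i_case, m_ctrl, i_ctrl), 2, 2, byrow = TRUE)
  p <- fisher_exact(tab, alternative = "less")$p
  out <- tibble(
    mature_fraction_case = f_case,
    mature_fraction_control = f_ctrl,
    fold_change = if (f_case > 0) f_ctrl / f_case else Inf,
    p_hypergeometric = p)
  attr(out, "case_hist") <- case_hist
  attr(out, "control_hist") <- control_hist
  class(out) <- c("maturity_result", class(out))
  out
}
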