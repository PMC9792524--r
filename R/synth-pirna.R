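#' Construct a piRNA read-length histogram
#'
#' A small container for small-RNA read counts by length on the 25-45 nt
#' support, with the spike-in read count used for normalization.
#'
#' @param counts Data frame with integer columns `length` (all within
#'   25..45) and `count` (>= 0), or a named numeric vector keyed by length.
#' @param spike_in_count Positive spike-in read count.
#' @return A `pirna_histogram` tibble with columns `length` (full 25..45
#'   support) and `count`, and attribute `spike_in_count`.
#' @export
pirna_histogram <- function(counts, spike_in_count) {
  if (is.numeric(counts) && !is.null(names(counts)))
    counts <- tibble(length = as.integer(names(counts)),
                     count = as.numeric(counts))
  assert_that(is.data.frame(counts) &&
                all(c("length", "count") %in% names(counts)),
              "`counts` needs columns length and count")
  assert_that(all(counts$length >= 25 & counts$length <= 45),
              "read lengths must lie within 25..45 nt")
  assert_that(all(counts$count >= 0), "counts must be non-negative")
  assert_scalar_num(spike_in_count, "spike_in_count", 0, strict_lower = TRUE)
  full <- tibble(length = 25:45)
  out <- dplyr::left_join(full, as_tibble(counts), by = "length")
  out$count[is.na(out$count)] <- 0
  attr(out, "spike_in_count") <- spike_in_count
  class(out) <- c("pirna_histogram", class(out))
  out
}

#' Simulate a matched case/control pair of piRNA length histograms
#'
#' Reads are mature (< 32 nt, lengths peaked at 29-30) with the requested
#' probability, otherwise immature (32-45 nt with decaying frequency);
#' the expected mature fraction of each histogram therefore equals the
#' requested fraction.
#'
#' @param mature_fraction_case,mature_fraction_control Target fractions of
#'   reads shorter than 32 nt, in [0, 1].
#' @param n_reads Reads per histogram (> 0).
#' @param spike_in_count Spike-in read count recorded verbatim on both
#'   histograms.
#' @param seed Integer seed.
#' @return A list with `case` and `control` [pirna_histogram()] objects.
#' @examples
#' pair <- generate_pirna_pair(0.55, 0.70, n_reads = 1e4, seed = 1)
#' mature_fraction(pair$case)
#' @export
generate_pirna_pair <- function(mature_fraction_case, mature_fraction_control,
                                n_reads = 1e5, spike_in_count = 1000,
                                seed = 1) {
  assert_scalar_num(mature_fraction_case, "mature_fraction_case", 0, 1)
  assert_scalar_num(mature_fraction_control, "mature_fraction_control", 0, 1)
  assert_that(is.numeric(n_reads) && length(n_reads) == 1 && n_reads > 0,
              "`n_reads` must be positive")
  n_reads <- as.integer(n_reads)
  mature_support <- 25:31
  mature_w <- c(0.02, 0.04, 0.08, 0.16, 0.30, 0.28, 0.12)
  immature_support <- 32:45
  immature_w <- 0.75^(seq_along(immature_support) - 1)
  one <- function(frac) {
    n_mat <- rbinom(1, n_reads, frac)
    lens <- c(sample(mature_support, n_mat, replace = TRUE, prob = mature_w),
              sample(immature_support, n_reads - n_mat, replace = TRUE,
                     prob = immature_w))
    cnt <- tabulate(factor(lens, levels = 25:45), nbins = 21)
    pirna_histogram(tibble(length = 25:45, count = cnt), spike_in_count)
  }
  with_seed(seed, list(case = one(mature_fraction_case),
                       control = one(mature_fraction_control)))
}
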