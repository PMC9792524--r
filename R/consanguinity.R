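# k-means++ initial centers for 1-D data
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  d2 <- (x - centers[1])^2
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(x), length(x))
    centers[j] <- x[sample.int(length(x), 1, prob = prob)]
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  sort(centers)
}

em_gaussian_1d <- function(x, k, max_iter, tol, min_sd) {
  n <- length(x)
  mu <- kmeanspp_centers(x, k)
  sigma <- rep(max(sd(x) / k, min_sd), k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:k, function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d)))
      return(list(ok = FALSE))
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    # EM guarantees monotone likelihood; a decrease flags a numeric defect
    if (ll < ll_old - 1e-8) return(list(ok = FALSE))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(list(ok = FALSE))
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    if (any(sigma < min_sd)) return(list(ok = FALSE)) # degenerate component
  }
  dens <- vapply(1:k, function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                 numeric(n))
  post <- dens / rowSums(dens)
  list(ok = TRUE, mu = mu, sigma = sigma, w = w, loglik = ll_old,
       loglik_trace = ll_trace, posterior = post)
}

#' Fit a five-class Gaussian mixture to ROH lengths
#'
#' Unsupervised clustering of runs-of-homozygosity segment lengths into `k`
#' classes by an unequal-variance 1-D Gaussian mixture on the natural-log
#' length scale (raw lengths are heavy-tailed). Expectation-maximisation
#' with k-means++ initialisation, best of `n_restarts` restarts by
#' log-likelihood; the per-iteration log-likelihood is checked to be
#' non-decreasing and degenerate components (vanishing spread) force a
#' restart. Components are sorted by mean, so class `k` is the
#' longest-length class - the autozygous stretches of recent inbreeding.
#'
#' @param lengths Positive segment lengths in bp (need at least `5 * k`).
#' @param k Number of classes (default 5).
#' @param n_restarts EM restarts (default 10).
#' @param max_iter,tol EM iteration budget and log-likelihood convergence
#'   tolerance.
#' @param seed Integer seed (selects restarts deterministically).
#' @return An `roh_mixture`: `components` tibble (`class`, `mean_log`,
#'   `sd_log`, `weight`), `assignment` (max-posterior class per segment),
#'   `posterior` matrix, `loglik`, `loglik_trace`, `n`.
#' @export
fit_length_mixture <- function(lengths, k = 5, n_restarts = 10,
                               max_iter = 300, tol = 1e-8, seed = 1) {
  assert_that(is.numeric(lengths) && all(lengths > 0),
              "`lengths` must be positive")
  assert_count(k, "k", min = 2L)
  assert_that(length(lengths) >= 5 * k,
              sprintf("need at least %d segments to fit %d classes", 5 * k, k))
  x <- log(lengths)
  if (sd(x) == 0)
    rlang::abort("all lengths identical: degenerate mixture")
  min_sd <- max(sd(x) * 1e-4, 1e-8)
  best <- NULL
  with_seed(seed, {
    attempts <- 0L
    budget <- n_restarts * 5L
    done <- 0L
    while (done < n_restarts && attempts < budget) {
      attempts <- attempts + 1L
      fit <- em_gaussian_1d(x, k, max_iter, tol, min_sd)
      if (!fit$ok) next # degenerate: retry with a fresh (jittered) init
      done <- done + 1L
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best))
    rlang::abort("EM failed to converge within the restart budget")
  ord <- order(best$mu)
  post <- best$posterior[, ord, drop = FALSE]
  assignment <- max.col(post, ties.method = "first")
  structure(
    list(components = tibble(class = seq_len(k),
                             mean_log = best$mu[ord],
                             sd_log = best$sigma[ord],
                             weight = best$w[ord]),
         assignment = assignment, posterior = post,
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         n = length(lengths), k = k),
    class = "roh_mixture")
}

#' @export
print.roh_mixture <- function(x, ...) {
  cat(sprintf("%d-class Gaussian mixture on log ROH length (n = %d, logLik = %.2f)\n",
              x$k, x$n, x$loglik))
  print(x$components)
  invisible(x)
}

#' Classify new segment lengths under a fitted mixture
#'
#' Maximum-posterior class for each length under the fitted components.
#'
#' @param mixture An [fit_length_mixture()] result.
#' @param lengths Positive lengths in bp.
#' @return Integer class labels (class `k` = longest class).
#' @export
classify_roh_lengths <- function(mixture, lengths) {
  assert_that(inherits(mixture, "roh_mixture"), "`mixture` must be an roh_mixture")
  x <- log(lengths)
  cmp <- mixture$components
  dens <- vapply(seq_len(nrow(cmp)), function(j)
    cmp$weight[j] * dnorm(x, cmp$mean_log[j], cmp$sd_log[j]),
    numeric(length(x)))
  max.col(matrix(dens, nrow = length(x)), ties.method = "first")
}

# total per-segment overlap (bp) with a set of (possibly overlapping)
# exclusion intervals, all 0-based half-open, chromosome-aware
segment_exclusion_bp <- function(segments, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(0, nrow(segments)))
  excl <- rep(0, nrow(segments))
  for (ch in unique(segments$chromosome)) {
    si <- which(segments$chromosome == ch)
    ri <- which(regions$chromosome == ch)
    if (!length(ri)) next
    seg_ir <- IRanges::IRanges(start = segments$start[si] + 1,
                               end = segments$end[si])
    reg_ir <- IRanges::reduce(IRanges::IRanges(start = regions$start[ri] + 1,
                                               end = regions$end[ri]))
    hits <- IRanges::findOverlaps(seg_ir, reg_ir)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      seg_ir[S4Vectors::queryHits(hits)], reg_ir[S4Vectors::subjectHits(hits)]))
    excl[si] <- excl[si] +
      as.numeric(tapply(ov, factor(S4Vectors::queryHits(hits),
                                   levels = seq_along(seg_ir)), sum,
                        default = 0))
  }
  excl
}

#' FROH from the longest ROH class
#'
#' Computes, per sample, the fraction of the autosome covered by runs of
#' homozygosity in the longest length class (class `k` of the fitted
#' mixture) - the class reflecting recent consanguinity. Overlap with
#' hemizygous regions (e.g. deletions from CNV calling), where apparent
#' homozygosity is an artifact, is subtracted before summing. All
#' intervals are 0-based half-open.
#'
#' @param segments Tibble of ROH segments: `sample_id`, `chromosome`,
#'   `start`, `end`.
#' @param mixture An [fit_length_mixture()] result used to classify
#'   segments by length.
#' @param autosome_length_bp Autosome length (> 0; default 2.88e9).
#' @param hemizygous_regions Optional tibble of intervals (`chromosome`,
#'   `start`, `end`) to exclude.
#' @return A `froh_result` tibble: `sample_id`, `class5_total_bp`,
#'   `excluded_bp`, `autosome_length_bp`, `froh`.
#' @export
froh <- function(segments, mixture, autosome_length_bp = 2.88e9,
                 hemizygous_regions = NULL) {
  assert_that(autosome_length_bp > 0, "`autosome_length_bp` must be positive")
  assert_that(all(segments$end > segments$start),
              "segments must satisfy end > start")
  seg <- as_tibble(segments)
  seg$length_bp <- seg$end - seg$start
  seg$class <- classify_roh_lengths(mixture, seg$length_bp)
  top <- seg[seg$class == mixture$k, ]
  top$excl <- if (nrow(top)) segment_exclusion_bp(top, hemizygous_regions)
              else numeric(0)
  out <- tibble(sample_id = unique(seg$sample_id)) |>
    dplyr::left_join(
      top |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(
          class5_total_bp = sum(.data$length_bp - .data$excl),
          excluded_bp = sum(.data$excl), .groups = "drop"),
      by = "sample_id")
  out$class5_total_bp[is.na(out$class5_total_bp)] <- 0
  out$excluded_bp[is.na(out$excluded_bp)] <- 0
  out$autosome_length_bp <- autosome_length_bp
  out$froh <- pmin(out$class5_total_bp / autosome_length_bp, 1)
  class(out) <- c("froh_result", class(out))
  out
}

#' Label samples as consanguineous by FROH
#'
#' A sample is labelled consanguineous when its FROH strictly exceeds the
#' threshold. The default 0.03 corresponds roughly to the expected
#' autozygosity of second-cousin offspring.
#'
#' @param froh_results A [froh()] result.
#' @param threshold FROH threshold in (0, 1), strict.
#' @return The input tibble with a logical `consanguineous` column.
#' @export
label_consanguineous <- function(froh_results, threshold = 0.03) {
  assert_scalar_num(threshold, "threshold", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  dplyr::mutate(froh_results, consanguineous = .data$froh > threshold)
}
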