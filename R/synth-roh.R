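#' Default ROH length-class mixture parameters
#'
#' Five log-normal length classes on the natural-log scale, ordered from
#' short ancient haplotypes to the long autozygous stretches produced by
#' recent inbreeding (class 5, mean ~10 Mb). Raw ROH length distributions
#' are heavy-tailed, which is why the mixture lives on log length.
#'
#' @return A tibble with columns `class`, `mean_log`, `sd_log`, `weight`.
#' @export
roh_class_params <- function() {
  tibble(class = 1:5,
         mean_log = log(c(1e5, 3e5, 1e6, 3e6, 1e7)),
         sd_log = rep(0.30, 5),
         weight = c(0.40, 0.25, 0.18, 0.12, 0.05))
}

#' Generate runs-of-homozygosity segments with planted consanguinity
#'
#' Draws per-individual ROH segments from a five-class log-normal length
#' mixture and places them without overlap on the 22 autosomes (0-based,
#' half-open intervals). Consanguineous individuals additionally receive
#' class-5 (longest class) segments until their planted FROH - the summed
#' class-5 length over the autosome length - exceeds `froh_threshold`.
#'
#' @param individuals Cohort tibble with `sample_id` and `consanguineous`.
#' @param class_params Tibble as [roh_class_params()]: 5 rows of
#'   `mean_log`, `sd_log` (> 0), `weight`.
#' @param segments_per_class Integer vector of length 5: baseline segment
#'   count per class for every individual.
#' @param autosome_length_bp Total autosome length (default 2.88e9).
#' @param froh_threshold Planted-consanguinity FROH floor (default 0.03).
#' @param seed Integer seed.
#' @return A tibble of segments: `sample_id`, `chromosome`, `start`, `end`,
#'   `length_bp`, and the planted truth label `class_planted`.
#' @export
generate_roh <- function(individuals,
                         class_params = roh_class_params(),
                         segments_per_class = c(12, 8, 5, 3, 0),
                         autosome_length_bp = 2.88e9,
                         froh_threshold = 0.03,
                         seed = 1) {
  assert_that(nrow(class_params) == 5 &&
                all(c("mean_log", "sd_log") %in% names(class_params)),
              "`class_params` must have 5 rows with mean_log and sd_log")
  assert_that(all(class_params$sd_log > 0), "component sds must be positive")
  assert_that(length(segments_per_class) == 5 && all(segments_per_class >= 0),
              "`segments_per_class` must be 5 non-negative counts")
  ord <- order(class_params$mean_log)
  class_params <- class_params[ord, ]
  class_params$class <- 1:5
  chrom_len <- autosome_length_bp / 22

  with_seed(seed, {
    out <- vector("list", nrow(individuals))
    for (i in seq_len(nrow(individuals))) {
      lens <- unlist(lapply(1:5, function(k) {
        n_k <- segments_per_class[k]
        if (n_k == 0) return(numeric(0))
        exp(rnorm(n_k, class_params$mean_log[k], class_params$sd_log[k]))
      }))
      classes <- rep(1:5, segments_per_class)
      if (isTRUE(individuals$consanguineous[i])) {
        need <- froh_threshold * autosome_length_bp * 1.1
        extra <- numeric(0)
        while (sum(c(lens[classes == 5], extra)) < need) {
          extra <- c(extra, exp(rnorm(1, class_params$mean_log[5],
                                      class_params$sd_log[5])))
        }
        lens <- c(lens, extra)
        classes <- c(classes, rep(5L, length(extra)))
      }
      if (length(lens) == 0) next
      lens <- round(pmax(lens, 1))
      chrom <- sample.int(22, length(lens), replace = TRUE)
      # lay segments left-to-right per chromosome with random gaps
      start <- integer(length(lens))
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        gaps <- round(runif(length(idx), 1e4, min(2e6, chrom_len / 20)))
        s <- cumsum(gaps + c(0, head(lens[idx], -1)))
        start[idx] <- s
      }
      out[[i]] <- tibble(
        sample_id = individuals$sample_id[i],
        chromosome = as.character(chrom),
        start = start, end = start + lens,
        length_bp = lens, class_planted = classes)
    }
    segs <- purrr::list_rbind(out[!vapply(out, is.null, logical(1))])
    if (is.null(segs) || nrow(segs) == 0)
      segs <- tibble(sample_id = character(), chromosome = character(),
                     start = numeric(), end = numeric(),
                     length_bp = numeric(), class_planted = integer())
    segs
  })
}
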