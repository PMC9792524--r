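#' Simulate a case/control cohort with planted monogenic findings
#'
#' Generates an all-male cohort of NOA cases and fertile controls together
#' with the annotated variant findings a prioritization pipeline would
#' consume, under a predominantly monogenic disease model: each case
#' independently receives one planted causal finding with its stratum's
#' discovery rate (consanguineous vs outbred), with the causal gene uniform
#' over a given pool. False-positive findings that pass all variant-level
#' filters but are not causal are added to cases and controls at `fp_rate`
#' per individual. Findings respect sex and chromosome: X- and Y-linked
#' findings are hemizygous, compound-heterozygous pairs arise only on
#' autosomes.
#'
#' Default rates are the study conditions of a large NOA exome cohort:
#' discovery 76.4% in consanguineous and 14.9% in non-consanguineous cases,
#' 7.8% of cases consanguineous, and up to one third of prioritized
#' variants being false positives (`fp_rate` default 0.10 per individual so
#' that FPs make up roughly a third of case findings at the outbred
#' discovery rate).
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param genes Gene universe from [generate_gene_universe()].
#' @param pool_gene_ids Character vector of causal-pool gene ids (subset of
#'   `genes$gene_id`).
#' @param consang_fraction Fraction of cases that are consanguineous.
#' @param discovery_rates Named vector with elements `consanguineous` and
#'   `outbred`: per-case probability of carrying a discoverable cause.
#' @param fp_rate Per-individual probability of a false-positive finding.
#' @param fp_within_pool If `TRUE`, false positives are drawn from the
#'   causal pool instead of background genes (used by recurrence
#'   false-positive bracketing experiments).
#' @param comphet_fraction_outbred Probability that an autosomal planted
#'   finding in an outbred case is a compound-heterozygous pair rather
#'   than a homozygous genotype (consanguineous cases are homozygous with
#'   probability 0.9).
#' @param seed Integer seed.
#' @return A list with elements `individuals` (tibble: `sample_id`, `sex`,
#'   `status`, `consanguineous`), `findings` (tibble of variant findings),
#'   and `truth` (list with `cases`: `sample_id`, `causal_gene_id`;
#'   `findings`: `finding_id`, `is_planted_true`).
#' @examples
#' genes <- generate_gene_universe(1000, seed = 1)
#' pool <- head(genes$gene_id[genes$chromosome %in% as.character(1:22)], 50)
#' sim <- generate_cohort(100, 100, genes, pool, seed = 2)
#' dplyr::count(sim$findings, model)
#' @export
generate_cohort <- function(n_cases, n_controls, genes, pool_gene_ids,
                            consang_fraction = 0.078,
                            discovery_rates = c(consanguineous = 0.764,
                                                outbred = 0.149),
                            fp_rate = 0.10,
                            fp_within_pool = FALSE,
                            comphet_fraction_outbred = 0.5,
                            seed = 1) {
  assert_count(n_cases, "n_cases", min = 0L)
  assert_count(n_controls, "n_controls", min = 0L)
  assert_that(is_tibble(genes) || is.data.frame(genes),
              "`genes` must be a gene-universe table")
  assert_that(all(pool_gene_ids %in% genes$gene_id),
              "`pool_gene_ids` must be a subset of the gene universe")
  assert_scalar_num(consang_fraction, "consang_fraction", 0, 1)
  assert_that(all(c("consanguineous", "outbred") %in% names(discovery_rates)) &&
                all(discovery_rates >= 0 & discovery_rates <= 1),
              "`discovery_rates` needs consanguineous and outbred entries in [0,1]")
  assert_scalar_num(fp_rate, "fp_rate", 0, 1)
  if (length(pool_gene_ids) == 0 && any(discovery_rates > 0))
    rlang::abort("empty causal pool with non-zero discovery rate")

  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  background <- setdiff(genes$gene_id, pool_gene_ids)

  with_seed(seed, {
    individuals <- tibble(
      sample_id = sprintf("S%05d", seq_len(n_cases + n_controls)),
      sex = "male",
      status = rep(c("case", "control"), c(n_cases, n_controls)),
      consanguineous = c(runif(n_cases) < consang_fraction,
                         rep(FALSE, n_controls))
    )

    fid <- 0L
    make_finding <- function(sample_id, gene_id, planted_true, consang) {
      fid <<- fid + 1L
      chrom <- unname(chrom_of[gene_id])
      model <- if (chrom == "X") "XL" else if (chrom == "Y") "YL" else {
        p_hom <- if (consang) 0.9 else 1 - comphet_fraction_outbred
        if (runif(1) < p_hom) "AR_hom" else "AR_comphet"
      }
      comphet <- model == "AR_comphet"
      key <- if (comphet)
        sprintf("%s:v%06d|v%06d", gene_id, fid, fid + 500000L)
      else sprintf("%s:v%06d", gene_id, fid)
      tibble(
        finding_id = sprintf("F%06d", fid),
        sample_id = sample_id, gene_id = gene_id, model = model,
        genotype_key = key,
        consequence = sample(c("lof", "missense"), 1, prob = c(0.5, 0.5)),
        popmax_maf = runif(1, 0, 0.009),
        psap_p = 10^runif(1, -8, -3.05),
        phase = if (comphet) "trans" else NA_character_,
        pair_distance_bp = if (comphet) sample(100:50000, 1) else NA_integer_,
        is_planted_true = planted_true
      )
    }

    cases <- individuals[individuals$status == "case", ]
    rate <- ifelse(cases$consanguineous,
                   discovery_rates[["consanguineous"]],
                   discovery_rates[["outbred"]])
    has_cause <- runif(nrow(cases)) < rate
    causal <- ifelse(has_cause,
                     sample(pool_gene_ids, nrow(cases), replace = TRUE),
                     NA_character_)

    rows <- list()
    for (i in seq_len(nrow(cases))) {
      if (has_cause[i])
        rows[[length(rows) + 1L]] <- make_finding(
          cases$sample_id[i], causal[i], TRUE, cases$consanguineous[i])
    }
    fp_pool <- if (fp_within_pool) pool_gene_ids else background
    if (fp_rate > 0 && length(fp_pool) > 0) {
      for (i in seq_len(nrow(individuals))) {
        if (runif(1) < fp_rate)
          rows[[length(rows) + 1L]] <- make_finding(
            individuals$sample_id[i],
            sample(fp_pool, 1), FALSE,
            individuals$consanguineous[i])
      }
    }
    findings <- if (length(rows)) purrr::list_rbind(rows) else
      tibble(finding_id = character(), sample_id = character(),
             gene_id = character(), model = character(),
             genotype_key = character(), consequence = character(),
             popmax_maf = numeric(), psap_p = numeric(),
             phase = character(), pair_distance_bp = integer(),
             is_planted_true = logical())

    truth <- list(
      cases = tibble(sample_id = cases$sample_id, causal_gene_id = causal),
      findings = tibble(finding_id = findings$finding_id,
                        is_planted_true = findings$is_planted_true)
    )
    findings$is_planted_true <- NULL
    list(individuals = individuals, findings = findings, truth = truth)
  })
}

#' Tally the observed recurrence rate from a findings table
#'
#' Counts, among case findings, the number of distinct genes hit and the
#' number hit in more than one unrelated case, giving the observed
#' recurrence statistic consumed by [estimate_pool_size()].
#'
#' @param findings A findings tibble (`sample_id`, `gene_id`, ...).
#' @param individuals Cohort tibble; only `status == "case"` samples count.
#' @param strata Optional subset of cases: `"all"`, `"outbred"` or
#'   `"consanguineous"`.
#' @return A tibble with `n_hits` (case findings), `n_distinct_genes`,
#'   `n_recurrent_genes`, `r_obs`.
#' @export
tally_recurrence <- function(findings, individuals,
                             strata = c("all", "outbred", "consanguineous")) {
  strata <- match.arg(strata)
  keep <- individuals$status == "case"
  if (strata == "outbred") keep <- keep & !individuals$consanguineous
  if (strata == "consanguineous") keep <- keep & individuals$consanguineous
  ids <- individuals$sample_id[keep]
  f <- findings[findings$sample_id %in% ids, ]
  per_gene <- dplyr::count(dplyr::distinct(f, .data$gene_id, .data$sample_id),
                           .data$gene_id)
  n_dist <- nrow(per_gene)
  n_rec <- sum(per_gene$n >= 2)
  tibble(n_hits = nrow(f), n_distinct_genes = n_dist,
         n_recurrent_genes = n_rec,
         r_obs = if (n_dist > 0) n_rec / n_dist else NA_real_)
}
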