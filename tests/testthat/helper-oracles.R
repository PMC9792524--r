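# independent oracles used across test files

# Fisher two-sided by explicit enumeration of all margin-fixed tables,
# using log-binomial coefficients (independent of stats::dhyper)
enumerate_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n_tot <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(n_tot, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force recurrence tally on a findings table
tally_recurrence_brute <- function(findings, case_ids) {
  f <- findings[findings$sample_id %in% case_ids, c("gene_id", "sample_id")]
  f <- unique(f)
  cnt <- table(f$gene_id)
  list(distinct = length(cnt), recurrent = sum(cnt >= 2),
       r = if (length(cnt)) sum(cnt >= 2) / length(cnt) else NA_real_)
}

# a small annotated gene table with known properties, for filter fixtures
toy_genes <- function() {
  tibble::tibble(
    gene_id = sprintf("TG%02d", 1:10),
    chromosome = c("1", "2", "3", "4", "5", "X", "X", "Y", "6", "7"),
    is_lof_tolerant_context = FALSE,
    testis_class = c("tissue_enriched", "none", "none", "group_enriched",
                     "none", "tissue_enhanced", "none", "none", "none",
                     "tissue_enhanced"),
    known_infertility = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                          FALSE, FALSE, FALSE),
    premeiotic_tpm = c(2, 0.8, 0.1, 1, 3, 1, 0.9, 0.9, 0.05, 2)
  )
}

toy_finding <- function(finding_id, sample_id, gene_id,
                        model = "AR_hom", key = NULL,
                        consequence = "lof", maf = 0.001, psap = 1e-5,
                        phase = NA_character_, dist = NA_integer_) {
  tibble::tibble(
    finding_id = finding_id, sample_id = sample_id, gene_id = gene_id,
    model = model,
    genotype_key = key %||% paste0(gene_id, ":", finding_id),
    consequence = consequence, popmax_maf = maf, psap_p = psap,
    phase = phase, pair_distance_bp = dist)
}

toy_cohort <- function(sample_ids, status = "case", consang = FALSE) {
  tibble::tibble(sample_id = sample_ids, sex = "male",
                 status = status,
                 consanguineous = rep_len(consang, length(sample_ids)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
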