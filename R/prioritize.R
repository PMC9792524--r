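#' Filter configuration for recessive-variant prioritization
#'
#' Thresholds of the variant filter cascade. Defaults are the values used
#' for discovery in a large NOA exome cohort: genotype p-value (PSAP-style)
#' at most 1e-3, population-max allele frequency at most 0.01, identical
#' homozygous/hemizygous genotypes discarded when carried by more than 3
#' individuals, identical compound-heterozygous pairs discarded when seen
#' in more than one case, and a gene-level enrichment filter flagging genes
#' where more than 3 distinct individuals carry distinct rare variants
#' with genotype p below 1e-4 (such pileups behave like technical
#' artifacts, not Mendelian disease).
#'
#' @param psap_p_max Maximum genotype p-value (exclusive upper: findings
#'   with `psap_p` above this are dropped).
#' @param popmax_maf_max Maximum population-max allele frequency.
#' @param identical_hom_hemi_max_individuals Identical hom/hemi genotype
#'   tolerated in at most this many individuals (strictly more is dropped).
#' @param identical_comphet_pair_max_individuals Same for identical
#'   compound-heterozygous pairs, counted over cases.
#' @param gene_enrichment_psap_p Genotype-p bound defining "rare pathogenic"
#'   variants for the gene-enrichment filter.
#' @param gene_enrichment_max_individuals Maximum tolerated count of
#'   distinct individuals with distinct qualifying variants per gene.
#' @param comphet_min_distance_bp Compound-heterozygous pairs closer than
#'   this (bp) are dropped (0 disables; 10 emulates cohorts excluding pairs
#'   within 10 bp).
#' @param premeiotic_tpm_min Minimum premeiotic single-cell TPM required of
#'   genes without elevated testis expression at the aggregation stage.
#' @param recessive_only Drop findings whose inheritance model is not one
#'   of `AR_hom`, `AR_comphet`, `XL`, `YL`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(psap_p_max = 1e-3,
                          popmax_maf_max = 0.01,
                          identical_hom_hemi_max_individuals = 3,
                          identical_comphet_pair_max_individuals = 1,
                          gene_enrichment_psap_p = 1e-4,
                          gene_enrichment_max_individuals = 3,
                          comphet_min_distance_bp = 0,
                          premeiotic_tpm_min = 0.5,
                          recessive_only = TRUE) {
  cfg <- list(psap_p_max = psap_p_max, popmax_maf_max = popmax_maf_max,
              identical_hom_hemi_max_individuals =
                identical_hom_hemi_max_individuals,
              identical_comphet_pair_max_individuals =
                identical_comphet_pair_max_individuals,
              gene_enrichment_psap_p = gene_enrichment_psap_p,
              gene_enrichment_max_individuals =
                gene_enrichment_max_individuals,
              comphet_min_distance_bp = comphet_min_distance_bp,
              premeiotic_tpm_min = premeiotic_tpm_min,
              recessive_only = isTRUE(recessive_only))
  nums <- cfg[names(cfg) != "recessive_only"]
  assert_that(all(vapply(nums, function(x)
    is.numeric(x) && length(x) == 1 && x >= 0, logical(1))),
    "all thresholds must be single non-negative numbers")
  assert_that(psap_p_max > 0 && psap_p_max <= 1 &&
                gene_enrichment_psap_p > 0 && gene_enrichment_psap_p <= 1,
              "probability thresholds must lie in (0, 1]")
  structure(cfg, class = "filter_config")
}

recessive_models <- c("AR_hom", "AR_comphet", "XL", "YL")

new_prioritization <- function(surviving, audit, stage, config, notes = NULL) {
  structure(list(surviving = surviving, audit = audit, stage = stage,
                 config = config, notes = notes,
                 gene_case_map = dplyr::distinct(surviving, .data$gene_id,
                                                 .data$sample_id)),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  dropped <- sum(!is.na(x$audit$dropped_by))
  cat(sprintf("Prioritization result (stage: %s)\n", x$stage))
  cat(sprintf("  %d findings in, %d surviving, %d dropped\n",
              nrow(x$audit), nrow(x$surviving), dropped))
  if (dropped > 0) {
    tab <- table(x$audit$dropped_by)
    for (nm in names(tab)) cat(sprintf("    %-22s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Variant-level filter cascade (stage 1)
#'
#' Applies the variant-level exclusion rules to a findings table: genotype
#' p-value and allele-frequency bounds, recurrence of identical
#' homozygous/hemizygous genotypes across individuals, recurrence of
#' identical compound-heterozygous pairs across cases, cis-configured or
#' too-close pairs, and the gene-level enrichment filter. Every rule is
#' evaluated as a predicate on the input table; a finding is dropped if it
#' fails any rule and the audit names the first failing rule in the fixed
#' order, so the surviving set does not depend on rule order and the stage
#' is idempotent.
#'
#' Compound-heterozygous findings without phase evidence are treated as
#' `phase = "unknown"` and retained (only demonstrated cis pairs are
#' excluded); their ids are reported in `notes$phase_unknown`.
#'
#' @param findings Findings tibble (see [generate_cohort()] for columns).
#' @param cohort Individuals tibble with `sample_id` and `status`.
#' @param cfg A [filter_config()].
#' @return A `prioritization_result`: `surviving` findings, `audit`
#'   (`finding_id`, `dropped_by`), `gene_case_map`, `notes`.
#' @export
apply_variant_filters <- function(findings, cohort, cfg = filter_config()) {
  assert_that(inherits(cfg, "filter_config"), "`cfg` must be a filter_config")
  assert_that(all(findings$sample_id %in% cohort$sample_id),
              "findings reference samples missing from `cohort`")
  f <- as_tibble(findings)
  if (!nrow(f)) {
    return(new_prioritization(f, tibble(finding_id = character(),
                                        dropped_by = character()),
                              "variant_filters", cfg))
  }
  is_comphet <- f$model == "AR_comphet"
  phase <- ifelse(is_comphet & (is.na(f$phase) | f$phase == ""),
                  "unknown", f$phase)
  phase_unknown <- f$finding_id[is_comphet & phase == "unknown"]

  case_ids <- cohort$sample_id[cohort$status == "case"]

  # identical hom/hemi genotype carried by > limit individuals
  homhemi <- f[f$model %in% c("AR_hom", "XL", "YL"), ]
  hot_keys <- homhemi |>
    dplyr::distinct(.data$genotype_key, .data$sample_id) |>
    dplyr::count(.data$genotype_key) |>
    dplyr::filter(.data$n > cfg$identical_hom_hemi_max_individuals) |>
    dplyr::pull(.data$genotype_key)

  # identical comphet pair observed in > limit cases
  ch <- f[is_comphet & f$sample_id %in% case_ids, ]
  hot_pairs <- ch |>
    dplyr::distinct(.data$genotype_key, .data$sample_id) |>
    dplyr::count(.data$genotype_key) |>
    dplyr::filter(.data$n > cfg$identical_comphet_pair_max_individuals) |>
    dplyr::pull(.data$genotype_key)

  # gene-level enrichment: distinct individuals carrying distinct
  # qualifying variants (bounded by a maximum matching of the two)
  qual <- f[f$psap_p < cfg$gene_enrichment_psap_p &
              f$popmax_maf < cfg$popmax_maf_max, ]
  hot_genes <- qual |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_ind = dplyr::n_distinct(.data$sample_id),
      n_var = dplyr::n_distinct(.data$genotype_key), .groups = "drop") |>
    dplyr::filter(pmin(.data$n_ind, .data$n_var) >
                    cfg$gene_enrichment_max_individuals) |>
    dplyr::pull(.data$gene_id)

  # rules in fixed audit order; each a logical "fails" vector on the input
  rules <- list(
    non_recessive_model = if (cfg$recessive_only)
      !(f$model %in% recessive_models) else rep(FALSE, nrow(f)),
    psap_p = f$psap_p > cfg$psap_p_max,
    popmax_maf = f$popmax_maf > cfg$popmax_maf_max,
    genotype_recurrence = f$genotype_key %in% hot_keys,
    comphet_recurrence = is_comphet & f$genotype_key %in% hot_pairs,
    comphet_cis = is_comphet & phase == "cis",
    comphet_proximity = is_comphet &
      !is.na(f$pair_distance_bp) &
      f$pair_distance_bp < cfg$comphet_min_distance_bp,
    gene_enrichment = f$gene_id %in% hot_genes
  )
  dropped_by <- rep(NA_character_, nrow(f))
  for (nm in names(rules)) {
    hit <- rules[[nm]] & is.na(dropped_by)
    dropped_by[hit] <- nm
  }
  audit <- tibble(finding_id = f$finding_id, dropped_by = dropped_by)
  new_prioritization(f[is.na(dropped_by), ], audit, "variant_filters", cfg,
                     notes = list(phase_unknown = phase_unknown))
}

#' Inheritance-mode-aware aggregation criteria (stage 2)
#'
#' Keeps only findings whose gene context is plausible for a Mendelian
#' spermatogenic defect. Autosomal findings must be loss-of-function, or in
#' a gene with known infertility evidence, or in a gene with elevated
#' testis expression. X-linked findings must be in a testis-elevated gene
#' *and* be loss-of-function or in a known infertility gene. Y-linked
#' findings must be loss-of-function. Any kept finding whose gene lacks
#' elevated testis expression must additionally show premeiotic single-cell
#' expression above `cfg$premeiotic_tpm_min`.
#'
#' @param stage1 A `prioritization_result` from [apply_variant_filters()]
#'   (or a raw findings tibble).
#' @param genes Gene universe tibble with `gene_id`, `chromosome`,
#'   `testis_class`, `known_infertility`, `premeiotic_tpm`.
#' @param cfg A [filter_config()].
#' @return A `prioritization_result` with stage `"aggregation"`; its audit
#'   covers the stage-1 input (earlier drops keep their rule names).
#' @export
apply_aggregation_criteria <- function(stage1, genes, cfg = filter_config()) {
  if (inherits(stage1, "prioritization_result")) {
    f <- stage1$surviving
    prev_audit <- stage1$audit
    notes <- stage1$notes
  } else {
    f <- as_tibble(stage1)
    prev_audit <- tibble(finding_id = f$finding_id,
                         dropped_by = NA_character_)
    notes <- NULL
  }
  assert_that(all(f$gene_id %in% genes$gene_id),
              "findings reference genes missing from `genes`")
  g <- genes[match(f$gene_id, genes$gene_id), ]
  known_chroms <- c(as.character(1:22), "X", "Y")
  if (nrow(g) && !all(g$chromosome %in% known_chroms))
    rlang::abort("unknown chromosome label in gene table")

  lof <- f$consequence == "lof"
  elevated <- g$testis_class != "none"
  is_x <- g$chromosome == "X"
  is_y <- g$chromosome == "Y"
  is_auto <- !is_x & !is_y

  keep <- rep(FALSE, nrow(f))
  rule <- rep(NA_character_, nrow(f))
  keep[is_auto] <- (lof | g$known_infertility | elevated)[is_auto]
  rule[is_auto & !keep] <- "aggregation_autosomal"
  keep[is_x] <- (elevated & (lof | g$known_infertility))[is_x]
  rule[is_x & !keep] <- "aggregation_x"
  keep[is_y] <- lof[is_y]
  rule[is_y & !keep] <- "aggregation_y"
  # premeiotic-expression backstop for kept findings in non-elevated genes
  fail_tpm <- keep & !elevated & !(g$premeiotic_tpm > cfg$premeiotic_tpm_min)
  keep[fail_tpm] <- FALSE
  rule[fail_tpm] <- "premeiotic_expression"

  audit <- prev_audit
  idx <- match(f$finding_id, audit$finding_id)
  audit$dropped_by[idx[!keep]] <- rule[!keep]
  new_prioritization(f[keep, ], audit, "aggregation", cfg, notes = notes)
}

#' Remove genes with prioritized variants in both cases and controls
#'
#' Genes whose surviving findings appear in both the case and the control
#' cohort are unlikely to be fully penetrant recessive causes of disease;
#' they are removed from both result sets, leaving disjoint gene sets.
#'
#' @param case_result,control_result `prioritization_result` objects from
#'   the same gene universe.
#' @return A list with updated `case` and `control` results; drops are
#'   audited under rule `"shared_gene"`.
#' @export
subtract_shared_genes <- function(case_result, control_result) {
  shared <- intersect(unique(case_result$surviving$gene_id),
                      unique(control_result$surviving$gene_id))
  prune <- function(res) {
    hit <- res$surviving$gene_id %in% shared
    idx <- match(res$surviving$finding_id[hit], res$audit$finding_id)
    res$audit$dropped_by[idx] <- "shared_gene"
    out <- new_prioritization(res$surviving[!hit, ], res$audit,
                              "subtraction", res$config, res$notes)
    out
  }
  list(case = prune(case_result), control = prune(control_result))
}

#' Per-stratum detection rates and the consanguinity contrast table
#'
#' For each cohort stratum (consanguineous vs outbred cases), the fraction
#' of cases with at least one surviving prioritized finding, plus the 2x2
#' table (detected / undetected by consanguinity) consumed by
#' [fisher_exact()].
#'
#' @param result A `prioritization_result`.
#' @param cohort Individuals tibble (`sample_id`, `status`,
#'   `consanguineous`).
#' @return A `detection_summary` list: `rates` tibble (`stratum`, `n`,
#'   `detected`, `rate`) and `contingency` (2x2 matrix, rows =
#'   consanguineous / outbred, cols = detected / undetected). Empty strata
#'   yield `NA` rates with a warning.
#' @export
detection_summary <- function(result, cohort) {
  cases <- cohort[cohort$status == "case", ]
  hit_samples <- unique(result$surviving$sample_id)
  detected <- cases$sample_id %in% hit_samples
  strat <- ifelse(cases$consanguineous, "consanguineous", "outbred")
  rates <- tibble(stratum = c("consanguineous", "outbred")) |>
    dplyr::mutate(
      n = vapply(.data$stratum, function(s) sum(strat == s), integer(1),
                 USE.NAMES = FALSE),
      detected = vapply(.data$stratum, function(s)
        sum(detected[strat == s]), integer(1), USE.NAMES = FALSE),
      rate = ifelse(.data$n > 0, .data$detected / .data$n, NA_real_))
  if (any(rates$n == 0))
    rlang::warn("empty stratum; its detection rate is undefined (NA)")
  contingency <- matrix(
    c(rates$detected[1], rates$n[1] - rates$detected[1],
      rates$detected[2], rates$n[2] - rates$detected[2]),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("consanguineous", "outbred"),
                    c("detected", "undetected")))
  structure(list(rates = rates, contingency = contingency),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detection summary by stratum\n")
  print(x$rates)
  invisible(x)
}
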