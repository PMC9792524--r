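#' Default end-to-end pipeline configuration
#'
#' Parameter blocks for every stage of [run_pipeline()]. Cohort rates
#' default to the study conditions (discovery 76.4% / 14.9% by
#' consanguinity, 7.8% consanguineous cases); sizes default to a small
#' demonstration cohort so a full run completes in well under two minutes
#' on one CPU. Any block entry can be overridden via `...` as a nested
#' list.
#'
#' @param ... Named blocks merged over the defaults, e.g.
#'   `cohort = list(n_cases = 500)`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genes = list(n_genes = 4000),
    cohort = list(n_cases = 250, n_controls = 250, consang_fraction = 0.078,
                  discovery_rates = c(consanguineous = 0.764,
                                      outbred = 0.149),
                  fp_rate = 0.10, pool_size = 120),
    filters = list(),
    architecture = list(grid = seq(10, 1000, by = 10), reps = 200,
                        projection_reps = 300, coverage_target = 0.5,
                        recurrence_k = 2),
    burden = list(threshold = 2.5e-6),
    roh = list(froh_threshold = 0.03),
    loadings = list(n_components = 20, set_size = 25, top_n = 50),
    pirna = list(mature_fraction_case = 0.55, mature_fraction_control = 0.70,
                 n_reads = 5e4, spike_in_count = 1000),
    tissue = list(n_genes = 80, n_tissues = 37)
  )
  over <- list(...)
  for (nm in names(over)) {
    assert_that(nm %in% names(cfg), sprintf("unknown config block `%s`", nm))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(over[[nm]]))
  }
  structure(cfg, class = "run_config")
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> prioritize -> burden -> architecture ->
#' expression -> piRNA -> FROH on a synthetic cohort with planted truth,
#' writing interchange TSV tables, a `summary.json` of headline statistics
#' and a `manifest.json` recording the seed, all parameters, and MD5
#' checksums of every written file. Deterministic given `config` and
#' `seed`: re-running with the same inputs reproduces the summary byte for
#' byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @param seed Integer master seed; every stochastic stage receives a
#'   deterministic child seed derived from it.
#' @return Invisibly, a list with the in-memory stage results and
#'   `summary` (the content of `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)

  # -- simulate ------------------------------------------------------------
  genes <- generate_gene_universe(config$genes$n_genes,
                                  seed = child_seed(seed, 1))
  # causal pool: aggregation-compatible autosomal/X/Y genes
  eligible <- genes$gene_id[genes$testis_class != "none" &
                              genes$chromosome %in% as.character(1:22)]
  pool <- head(eligible, config$cohort$pool_size)
  sim <- generate_cohort(
    config$cohort$n_cases, config$cohort$n_controls, genes, pool,
    consang_fraction = config$cohort$consang_fraction,
    discovery_rates = config$cohort$discovery_rates,
    fp_rate = config$cohort$fp_rate,
    seed = child_seed(seed, 2))
  files <- c(files,
             write_stage_tsv(genes, out_dir, "genes"),
             write_stage_tsv(sim$individuals, out_dir, "individuals"),
             write_stage_tsv(sim$findings, out_dir, "findings"),
             write_stage_tsv(sim$truth$cases, out_dir, "truth_cases"))

  # -- prioritize ----------------------------------------------------------
  cfg <- do.call(filter_config, config$filters)
  split_f <- split(sim$findings,
                   sim$findings$sample_id %in%
                     sim$individuals$sample_id[sim$individuals$status == "case"])
  case_f <- split_f[["TRUE"]] %||% sim$findings[0, ]
  ctrl_f <- split_f[["FALSE"]] %||% sim$findings[0, ]
  pri_case <- apply_aggregation_criteria(
    apply_variant_filters(case_f, sim$individuals, cfg), genes, cfg)
  pri_ctrl <- apply_aggregation_criteria(
    apply_variant_filters(ctrl_f, sim$individuals, cfg), genes, cfg)
  sub <- subtract_shared_genes(pri_case, pri_ctrl)
  det <- detection_summary(sub$case, sim$individuals)
  files <- c(files,
             write_stage_tsv(sub$case$surviving, out_dir, "prioritized_case"),
             write_stage_tsv(sub$case$audit, out_dir, "audit_case"),
             write_stage_tsv(det$rates, out_dir, "detection_rates"))
  fisher_det <- fisher_exact(det$contingency)

  # -- burden --------------------------------------------------------------
  n_cases <- sum(sim$individuals$status == "case")
  n_ctrl <- sum(sim$individuals$status == "control")
  single <- function(res) dplyr::filter(res$surviving, .data$model != "AR_comphet")
  counts <- dplyr::full_join(
    single(sub$case) |> dplyr::distinct(.data$gene_id, .data$sample_id) |>
      dplyr::count(.data$gene_id, name = "case_carriers"),
    single(sub$control) |> dplyr::distinct(.data$gene_id, .data$sample_id) |>
      dplyr::count(.data$gene_id, name = "control_carriers"),
    by = "gene_id") |>
    dplyr::mutate(across(c("case_carriers", "control_carriers"),
                         ~ dplyr::coalesce(.x, 0L)))
  burden <- if (nrow(counts))
    burden_scan(counts, n_cases, n_ctrl, threshold = config$burden$threshold)
  else NULL
  if (!is.null(burden))
    files <- c(files, write_stage_tsv(burden, out_dir, "burden"))

  # -- architecture --------------------------------------------------------
  rec <- tally_recurrence(sub$case$surviving, sim$individuals, "outbred")
  arch <- config$architecture
  pool_est <- if (!is.na(rec$r_obs) && rec$n_hits >= 2)
    estimate_pool_size(rec$r_obs, rec$n_hits, grid = arch$grid,
                       reps = arch$reps, seed = child_seed(seed, 3))
  else NULL
  proj <- if (!is.null(pool_est))
    project_cohort_size(pool_est$p_hat,
                        config$cohort$discovery_rates[["outbred"]],
                        coverage_target = arch$coverage_target,
                        recurrence_k = arch$recurrence_k,
                        reps = arch$projection_reps,
                        seed = child_seed(seed, 4))
  else NULL
  if (!is.null(pool_est))
    files <- c(files,
               write_stage_tsv(pool_est$objective_curve, out_dir,
                               "pool_objective"),
               write_stage_tsv(proj$curve, out_dir, "projection_curve"))

  # -- expression ----------------------------------------------------------
  ld_cfg <- config$loadings
  planted <- list(`1` = pool[seq_len(min(ld_cfg$set_size, length(pool)))])
  loadings <- generate_loadings(ld_cfg$n_components, genes$gene_id, planted,
                                seed = child_seed(seed, 5))
  sets <- component_gene_sets(loadings, top_n = ld_cfg$top_n)
  prof <- profile_counts(unique(sub$case$surviving$gene_id), sets)
  enr <- component_enrichment(planted[[1]], sets[[1]], nrow(genes))
  files <- c(files, write_stage_tsv(prof, out_dir, "component_profile"))

  # tissue-specificity round trip on a gene subsample
  t_cfg <- config$tissue
  cls <- c("tissue_enriched", "group_enriched", "tissue_enhanced", "none")
  planted_cls <- setNames(
    rep(cls, length.out = t_cfg$n_genes),
    head(genes$gene_id, t_cfg$n_genes))
  tmat <- generate_tissue_matrix(planted_cls, n_tissues = t_cfg$n_tissues,
                                 seed = child_seed(seed, 6))
  tcls <- classify_tissue_specificity(tmat)
  tissue_agreement <- mean(tcls$class == planted_cls[tcls$gene_id])

  # -- piRNA ---------------------------------------------------------------
  p_cfg <- config$pirna
  pair <- generate_pirna_pair(p_cfg$mature_fraction_case,
                              p_cfg$mature_fraction_control,
                              n_reads = p_cfg$n_reads,
                              spike_in_count = p_cfg$spike_in_count,
                              seed = child_seed(seed, 7))
  maturity <- compare_maturity(pair$case, pair$control)
  files <- c(files, write_stage_tsv(as_tibble(maturity), out_dir, "pirna"))

  # -- FROH ----------------------------------------------------------------
  roh <- generate_roh(sim$individuals,
                      froh_threshold = config$roh$froh_threshold,
                      seed = child_seed(seed, 8))
  mix <- fit_length_mixture(roh$length_bp, seed = child_seed(seed, 9))
  fr <- froh(roh, mix)
  fr <- label_consanguineous(fr, threshold = config$roh$froh_threshold)
  truth_consang <- sim$individuals$consanguineous[
    match(fr$sample_id, sim$individuals$sample_id)]
  froh_sensitivity <- if (any(truth_consang))
    mean(fr$consanguineous[truth_consang]) else NA_real_
  files <- c(files, write_stage_tsv(fr, out_dir, "froh"))

  # -- summary + manifest --------------------------------------------------
  summary <- list(
    detection = list(
      rates = det$rates,
      fisher_p = fisher_det$p),
    burden = list(
      n_genes_tested = if (is.null(burden)) 0L else nrow(burden),
      n_significant = if (is.null(burden)) 0L
                      else sum(burden$significant_two_stage)),
    architecture = list(
      r_obs = rec$r_obs, n_hits = rec$n_hits,
      pool_size_truth = length(pool),
      p_hat = if (is.null(pool_est)) NA else pool_est$p_hat,
      n_required = if (is.null(proj)) NA else proj$n_required),
    expression = list(
      component1_enrichment_p = enr$p,
      tissue_class_agreement = tissue_agreement),
    pirna = as.list(as_tibble(maturity)),
    froh = list(sensitivity = froh_sensitivity,
                n_segments = nrow(roh))
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  files <- c(files, summary_path)

  manifest <- list(
    package = "noaexome",
    version = as.character(utils::packageVersion("noaexome")),
    seed = seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genes = genes, sim = sim, case = sub$case,
                 control = sub$control, detection = det, burden = burden,
                 pool_estimate = pool_est, projection = proj,
                 profile = prof, maturity = maturity, froh = fr,
                 summary = summary))
}

#' Verify the integrity of a pipeline run directory
#'
#' Recomputes the MD5 checksum of every file listed in the run's
#' `manifest.json` and fails if any file is missing or was modified.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return Invisibly `TRUE` on success; errors on mismatch.
#' @export
verify_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  assert_that(file.exists(manifest_path), "no manifest.json in `run_dir`")
  manifest <- jsonlite::read_json(manifest_path)
  for (nm in names(manifest$checksums)) {
    path <- file.path(run_dir, nm)
    if (!file.exists(path))
      rlang::abort(sprintf("missing pipeline output: %s", nm))
    actual <- unname(tools::md5sum(path))
    if (!identical(actual, manifest$checksums[[nm]]))
      rlang::abort(sprintf("checksum mismatch for %s: file was modified", nm))
  }
  invisible(TRUE)
}
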