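make_filter_fixture <- function() {
  cohort <- toy_cohort(sprintf("P%02d", 1:6))
  findings <- dplyr::bind_rows(
    toy_finding("f1", "P01", "TG01", maf = 0.02),          # fails MAF
    toy_finding("f2", "P02", "TG02", maf = 0.02),          # fails MAF
    toy_finding("f3", "P01", "TG03", key = "TG03:shared"), # shared hom x4
    toy_finding("f4", "P02", "TG03", key = "TG03:shared"),
    toy_finding("f5", "P03", "TG03", key = "TG03:shared"),
    toy_finding("f6", "P04", "TG03", key = "TG03:shared"),
    toy_finding("f7", "P05", "TG04", model = "AR_comphet",
                phase = "cis", dist = 5000),               # cis pair
    toy_finding("f8", "P05", "TG01"),                      # clean
    toy_finding("f9", "P06", "TG04", model = "AR_comphet",
                phase = "trans", dist = 2000)              # clean
  )
  list(cohort = cohort, findings = findings)
}

test_that("variant-level rules drop findings with the first failing rule named", {
  fx <- make_filter_fixture()
  res <- apply_variant_filters(fx$findings, fx$cohort)

  expect_setequal(res$surviving$finding_id, c("f8", "f9"))
  audit <- setNames(res$audit$dropped_by, res$audit$finding_id)
  expect_identical(unname(audit[c("f1", "f2")]),
                   rep("popmax_maf", 2))
  expect_identical(unname(audit[c("f3", "f4", "f5", "f6")]),
                   rep("genotype_recurrence", 4))
  expect_identical(unname(audit[["f7"]]), "comphet_cis")
  expect_true(all(is.na(audit[c("f8", "f9")])))

  # a high genotype p-value is dropped under rule psap_p
  hi <- toy_finding("h1", "P01", "TG01", psap = 0.01)
  r2 <- apply_variant_filters(hi, fx$cohort)
  expect_identical(r2$audit$dropped_by, "psap_p")

  # an identical compound-het pair in exactly one case is retained
  one_pair <- toy_finding("c1", "P01", "TG05", model = "AR_comphet",
                          key = "TG05:a|b", phase = "trans", dist = 100)
  expect_identical(
    apply_variant_filters(one_pair, fx$cohort)$surviving$finding_id, "c1")
  # ... but the same pair in two cases is removed from both
  two_pair <- dplyr::bind_rows(
    one_pair, toy_finding("c2", "P02", "TG05", model = "AR_comphet",
                          key = "TG05:a|b", phase = "trans", dist = 100))
  r3 <- apply_variant_filters(two_pair, fx$cohort)
  expect_identical(nrow(r3$surviving), 0L)
  expect_identical(unique(r3$audit$dropped_by), "comphet_recurrence")
})

test_that("gene-enrichment rule removes pileup genes; proximity and phase handled", {
  cohort <- toy_cohort(sprintf("P%02d", 1:6))
  # 4 distinct individuals with 4 distinct ultra-rare variants in TG05
  pile <- purrr::map(1:4, function(i)
    toy_finding(paste0("e", i), sprintf("P%02d", i), "TG05",
                key = sprintf("TG05:v%d", i), psap = 1e-6)) |>
    purrr::list_rbind()
  clean <- toy_finding("e9", "P05", "TG01", psap = 1e-6)
  res <- apply_variant_filters(dplyr::bind_rows(pile, clean), cohort)
  expect_setequal(res$surviving$finding_id, "e9")
  expect_identical(unique(res$audit$dropped_by[res$audit$finding_id != "e9"]),
                   "gene_enrichment")
  # 4 individuals sharing ONE variant is genotype recurrence, not enrichment
  shared <- purrr::map(1:4, function(i)
    toy_finding(paste0("s", i), sprintf("P%02d", i), "TG05",
                key = "TG05:same", psap = 1e-6)) |>
    purrr::list_rbind()
  res2 <- apply_variant_filters(shared, cohort)
  expect_identical(unique(res2$audit$dropped_by), "genotype_recurrence")

  # close pairs removed only when a minimum distance is configured
  near <- toy_finding("n1", "P01", "TG04", model = "AR_comphet",
                      phase = "trans", dist = 4)
  expect_identical(nrow(apply_variant_filters(near, cohort)$surviving), 1L)
  cfg10 <- filter_config(comphet_min_distance_bp = 10)
  r10 <- apply_variant_filters(near, cohort, cfg10)
  expect_identical(r10$audit$dropped_by, "comphet_proximity")

  # missing phase is treated as unknown and retained, with a note
  nop <- toy_finding("p1", "P01", "TG04", model = "AR_comphet",
                     phase = NA_character_, dist = 1000)
  rp <- apply_variant_filters(nop, cohort)
  expect_identical(rp$surviving$finding_id, "p1")
  expect_identical(rp$notes$phase_unknown, "p1")
})

test_that("aggregation criteria follow inheritance mode and gene context", {
  genes <- toy_genes()
  cohort <- toy_cohort(sprintf("P%02d", 1:8))
  f <- dplyr::bind_rows(
    # autosomal missense, no infertility evidence, no testis expression,
    # low premeiotic expression: meets no criterion
    toy_finding("a1", "P01", "TG03", consequence = "missense"),
    # autosomal missense in known-infertility gene with premeiotic backstop
    toy_finding("a2", "P02", "TG02", consequence = "missense"),
    # autosomal lof in unannotated, premeiotic-low gene: lof criterion but
    # fails the premeiotic backstop
    toy_finding("a3", "P03", "TG09", consequence = "lof"),
    # Y-linked lof kept; Y-linked missense dropped
    toy_finding("y1", "P04", "TG08", model = "YL", consequence = "lof"),
    toy_finding("y2", "P05", "TG08", model = "YL", consequence = "missense"),
    # X-linked: testis-elevated + known infertility kept even if missense
    toy_finding("x1", "P06", "TG06", model = "XL", consequence = "missense"),
    # X-linked lof in non-elevated gene dropped (X needs elevation)
    toy_finding("x2", "P07", "TG07", model = "XL", consequence = "lof"),
    # autosomal missense in testis-enriched gene kept
    toy_finding("a4", "P08", "TG01", consequence = "missense")
  )
  res <- apply_aggregation_criteria(f, genes)
  expect_setequal(res$surviving$finding_id, c("a2", "y1", "x1", "a4"))
  audit <- setNames(res$audit$dropped_by, res$audit$finding_id)
  expect_identical(unname(audit[["a1"]]), "aggregation_autosomal")
  expect_identical(unname(audit[["a3"]]), "premeiotic_expression")
  expect_identical(unname(audit[["y2"]]), "aggregation_y")
  expect_identical(unname(audit[["x2"]]), "aggregation_x")

  bad <- toy_finding("b1", "P01", "TG01")
  genes_bad <- dplyr::mutate(genes, chromosome = dplyr::if_else(
    gene_id == "TG01", "MT", chromosome))
  expect_error(apply_aggregation_criteria(bad, genes_bad), "chromosome")
})

test_that("case/control gene subtraction is symmetric set algebra", {
  cohort <- toy_cohort(c("P01", "P02", "P03", "P04"),
                       status = c("case", "case", "control", "control"))
  mk <- function(ids, samples, genes) {
    purrr::pmap(list(ids, samples, genes),
                function(i, s, g) toy_finding(i, s, g)) |>
      purrr::list_rbind() |>
      apply_variant_filters(cohort)
  }
  case <- mk(c("u1", "u2", "u3"), c("P01", "P01", "P02"),
             c("TG01", "TG02", "TG04"))
  ctrl <- mk(c("v1", "v2"), c("P03", "P04"), c("TG02", "TG05"))
  out <- subtract_shared_genes(case, ctrl)
  expect_setequal(out$case$surviving$gene_id, c("TG01", "TG04"))
  expect_setequal(out$control$surviving$gene_id, "TG05")
  expect_length(intersect(out$case$surviving$gene_id,
                          out$control$surviving$gene_id), 0)
  aud <- setNames(out$case$audit$dropped_by, out$case$audit$finding_id)
  expect_identical(unname(aud[["u2"]]), "shared_gene")

  # disjoint inputs unchanged; identical inputs both emptied
  disj <- subtract_shared_genes(case, mk("w1", "P03", "TG09"))
  expect_identical(disj$case$surviving, case$surviving)
  same <- subtract_shared_genes(case, mk(c("z1", "z2", "z3"),
                                         c("P03", "P03", "P04"),
                                         c("TG01", "TG02", "TG04")))
  expect_identical(nrow(same$case$surviving), 0L)
  expect_identical(nrow(same$control$surviving), 0L)
})

test_that("detection summary reproduces stratum rates and the 2x2 table", {
  # cohort shaped like the study: 72 consanguineous cases with 55 detected,
  # 852 outbred with 127 detected
  ids_c <- sprintf("C%03d", 1:72)
  ids_o <- sprintf("O%03d", 1:852)
  cohort <- dplyr::bind_rows(toy_cohort(ids_c, consang = TRUE),
                             toy_cohort(ids_o, consang = FALSE))
  hits <- c(ids_c[1:55], ids_o[1:127])
  # psap above the enrichment bound so the shared gene is not flagged
  findings <- purrr::imap(hits, function(s, i)
    toy_finding(paste0("d", i), s, "TG01", psap = 5e-4)) |>
    purrr::list_rbind()
  res <- apply_variant_filters(findings, cohort)
  det <- detection_summary(res, cohort)
  expect_equal(det$rates$rate[det$rates$stratum == "consanguineous"],
               55 / 72)
  expect_equal(det$rates$rate[det$rates$stratum == "outbred"], 127 / 852)
  expect_identical(unname(det$contingency),
                   matrix(c(55L, 17L, 127L, 725L), 2, byrow = TRUE))

  # all cases detected -> rate 1; empty stratum flagged
  small <- toy_cohort(c("P01", "P02"))
  r <- apply_variant_filters(dplyr::bind_rows(
    toy_finding("q1", "P01", "TG01"), toy_finding("q2", "P02", "TG01")),
    small)
  expect_warning(d2 <- detection_summary(r, small), "empty stratum")
  expect_equal(d2$rates$rate[d2$rates$stratum == "outbred"], 1)
})

test_that("cascade is idempotent, order-insensitive, monotone, and audited", {
  genes <- generate_gene_universe(800, seed = 11)
  pool <- head(genes$gene_id[genes$chromosome %in% as.character(1:22)], 40)
  sim <- generate_cohort(150, 150, genes, pool, fp_rate = 0.3, seed = 12)
  cfg <- filter_config()
  s1 <- apply_variant_filters(sim$findings, sim$individuals, cfg)

  # idempotence
  s1b <- apply_variant_filters(s1$surviving, sim$individuals, cfg)
  expect_identical(s1b$surviving, s1$surviving)

  # order independence: survival equals the conjunction of per-rule
  # predicates evaluated independently on the input
  f <- sim$findings
  case_ids <- sim$individuals$sample_id[sim$individuals$status == "case"]
  keys_hot <- names(which(table(unique(
    f[f$model != "AR_comphet", c("genotype_key", "sample_id")])$genotype_key)
    > cfg$identical_hom_hemi_max_individuals))
  ch <- unique(f[f$model == "AR_comphet" & f$sample_id %in% case_ids,
                 c("genotype_key", "sample_id")])
  pairs_hot <- names(which(table(ch$genotype_key) >
                             cfg$identical_comphet_pair_max_individuals))
  qual <- f[f$psap_p < cfg$gene_enrichment_psap_p &
              f$popmax_maf < cfg$popmax_maf_max, ]
  byg <- split(qual, qual$gene_id)
  genes_hot <- names(byg)[vapply(byg, function(d)
    min(length(unique(d$sample_id)), length(unique(d$genotype_key))) >
      cfg$gene_enrichment_max_individuals, logical(1))]
  pass <- f$psap_p <= cfg$psap_p_max &
    f$popmax_maf <= cfg$popmax_maf_max &
    !(f$genotype_key %in% keys_hot) &
    !(f$genotype_key %in% pairs_hot) &
    !(f$model == "AR_comphet" & !is.na(f$phase) & f$phase == "cis") &
    !(f$gene_id %in% genes_hot)
  expect_setequal(s1$surviving$finding_id, f$finding_id[pass])

  # audit partitions the input
  expect_identical(nrow(s1$audit), nrow(f))
  expect_identical(nrow(s1$surviving) + sum(!is.na(s1$audit$dropped_by)),
                   nrow(f))

  # monotonicity: relaxing thresholds never shrinks the surviving set
  relaxed <- filter_config(psap_p_max = 1, popmax_maf_max = 1,
                           identical_hom_hemi_max_individuals = 100,
                           identical_comphet_pair_max_individuals = 100,
                           gene_enrichment_max_individuals = 100)
  s_rel <- apply_variant_filters(sim$findings, sim$individuals, relaxed)
  expect_true(all(s1$surviving$finding_id %in% s_rel$surviving$finding_id))
})

test_that("with no false positives, no planted-true finding is falsely rejected", {
  genes <- generate_gene_universe(5000, seed = 21)
  compatible <- genes$testis_class != "none" &
    genes$chromosome %in% as.character(1:22)
  pool <- head(genes$gene_id[compatible], 300)
  sim <- generate_cohort(600, 0, genes, pool, fp_rate = 0, seed = 22)
  cfg <- filter_config()
  s2 <- apply_aggregation_criteria(
    apply_variant_filters(sim$findings, sim$individuals, cfg), genes, cfg)
  truth <- sim$truth$findings
  planted_ids <- truth$finding_id[truth$is_planted_true]
  expect_setequal(s2$surviving$finding_id, planted_ids)

  # planted detection rate recovered within binomial noise
  sim2 <- generate_cohort(800, 0, genes, pool, consang_fraction = 0,
                          discovery_rates = c(consanguineous = 0.2,
                                              outbred = 0.2),
                          fp_rate = 0, seed = 23)
  s <- apply_aggregation_criteria(
    apply_variant_filters(sim2$findings, sim2$individuals, cfg), genes, cfg)
  # all-outbred cohort: the consanguineous stratum is empty by design
  det <- suppressWarnings(detection_summary(s, sim2$individuals))
  rate <- det$rates$rate[det$rates$stratum == "outbred"]
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 800))
})
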