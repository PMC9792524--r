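test_that("gene universe generation is seeded, tallied, and validated", {
  expect_error(generate_gene_universe(0), "n_genes")
  expect_error(generate_gene_universe(10, class_proportions = c(
    tissue_enriched = 0.5, group_enriched = 0.5, tissue_enhanced = 0.5,
    none = 0.5)), "simplex")

  g1 <- generate_gene_universe(1000, seed = 1)
  g2 <- generate_gene_universe(1000, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_gene_universe(1000, seed = 2)))
  expect_false(anyDuplicated(g1$gene_id) > 0)
  expect_true(all(g1$premeiotic_tpm >= 0))

  # class tally against direct count: binomial 3 sigma around n * fraction
  frac <- 0.10
  g3 <- generate_gene_universe(
    1000, class_proportions = c(tissue_enriched = 0, group_enriched = 0,
                                tissue_enhanced = frac, none = 1 - frac),
    seed = 3)
  n_enh <- sum(g3$testis_class == "tissue_enhanced")
  expect_lt(abs(n_enh - 1000 * frac), 3 * sqrt(1000 * frac * (1 - frac)))
  # and the tally is exactly what a direct scan of the table yields
  expect_identical(n_enh, length(which(g3$testis_class == "tissue_enhanced")))
})

test_that("cohort generation plants findings at the stratum discovery rates", {
  genes <- generate_gene_universe(2000, seed = 1)
  auto <- genes$gene_id[genes$chromosome %in% as.character(1:22)]
  pool <- head(auto, 50)

  zero <- generate_cohort(20, 20, genes, pool,
                          discovery_rates = c(consanguineous = 0,
                                              outbred = 0),
                          fp_rate = 0, seed = 1)
  expect_identical(nrow(zero$findings), 0L)

  expect_error(generate_cohort(10, 0, genes, character(0), seed = 1),
               "empty causal pool")

  # 852 outbred cases at the study's 14.9% discovery rate: planted-true
  # count within 3 sigma of the binomial expectation (~127)
  sim <- generate_cohort(852, 0, genes, pool, consang_fraction = 0,
                         discovery_rates = c(consanguineous = 0.764,
                                             outbred = 0.149),
                         fp_rate = 0, seed = 7)
  n_true <- sum(sim$truth$findings$is_planted_true)
  expect_lt(abs(n_true - 852 * 0.149), 3 * sqrt(852 * 0.149 * 0.851))
  # truth table is consistent: planted-true findings sit in the causal gene
  truth <- dplyr::left_join(sim$findings, sim$truth$findings,
                            by = "finding_id") |>
    dplyr::left_join(sim$truth$cases, by = "sample_id")
  planted <- truth[truth$is_planted_true, ]
  expect_true(all(planted$gene_id == planted$causal_gene_id))
  # at most one causal gene per case
  expect_lte(max(table(planted$sample_id)), 1L)
})

test_that("recurrence tallies match a brute-force scan of the table", {
  genes <- generate_gene_universe(1000, seed = 2)
  pool <- head(genes$gene_id[genes$chromosome %in% as.character(1:22)], 5)
  sim <- generate_cohort(150, 0, genes, pool, consang_fraction = 1,
                         discovery_rates = c(consanguineous = 0.7,
                                             outbred = 0),
                         fp_rate = 0, seed = 3)
  case_ids <- sim$individuals$sample_id[sim$individuals$status == "case"]
  oracle <- tally_recurrence_brute(sim$findings, case_ids)
  got <- tally_recurrence(sim$findings, sim$individuals)
  expect_identical(got$n_distinct_genes, oracle$distinct)
  expect_identical(got$n_recurrent_genes, as.integer(oracle$recurrent))
  expect_equal(got$r_obs, oracle$r)
  expect_gt(got$n_hits, 80) # pool of 5 with ~100 hits recurs heavily
  expect_equal(got$n_recurrent_genes, 5L)
})

test_that("findings respect male sex chromosomes", {
  genes <- generate_gene_universe(1500, seed = 4)
  pool <- head(genes$gene_id, 200) # all chromosomes, X and Y included
  sim <- generate_cohort(400, 100, genes, pool,
                         discovery_rates = c(consanguineous = 0.764,
                                             outbred = 0.5),
                         fp_rate = 0.2, seed = 5)
  chrom <- genes$chromosome[match(sim$findings$gene_id, genes$gene_id)]
  comphet <- sim$findings$model == "AR_comphet"
  # no heterozygous pair on X or Y, ever
  expect_false(any(comphet & chrom %in% c("X", "Y")))
  # hemizygous models only on the sex chromosomes
  expect_true(all(sim$findings$model[chrom == "X"] == "XL"))
  expect_true(all(sim$findings$model[chrom == "Y"] == "YL"))
  # phase defined iff compound heterozygous
  expect_true(all(!is.na(sim$findings$phase[comphet])))
  expect_true(all(is.na(sim$findings$phase[!comphet])))
})

test_that("ROH generation plants separable classes and consanguinity", {
  ind <- toy_cohort(sprintf("R%02d", 1:30),
                    consang = rep(c(TRUE, FALSE), c(6, 24)))
  none <- generate_roh(ind, segments_per_class = c(0, 0, 0, 0, 0),
                       seed = 1)
  expect_identical(nrow(none[!ind$consanguineous[match(none$sample_id,
                                                       ind$sample_id)], ]),
                   0L)
  expect_error(generate_roh(ind, class_params = dplyr::mutate(
    roh_class_params(), sd_log = 0)), "positive")

  params <- dplyr::mutate(roh_class_params(), sd_log = 0.2)
  roh <- generate_roh(ind, class_params = params,
                      segments_per_class = c(10, 8, 6, 4, 2), seed = 2)
  # segments are valid, non-overlapping intervals per sample/chromosome
  expect_true(all(roh$end > roh$start))
  overlaps <- roh |>
    dplyr::group_by(sample_id, chromosome) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(start) >= head(end - start, -1) |
                                dplyr::n() == 1), .groups = "drop")
  expect_true(all(overlaps$ok))
  # planted class labels recoverable by nearest mean on log length
  # (components > 3 sd apart)
  expect_true(all(diff(params$mean_log) > 3 * params$sd_log[1]))
  nearest <- apply(abs(outer(log(roh$length_bp), params$mean_log, "-")),
                   1, which.min)
  expect_gte(mean(nearest == roh$class_planted), 0.95)
  # consanguineous samples carry class-5 mass above the FROH threshold
  class5 <- roh[roh$class_planted == 5, ] |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(length_bp))
  consang_ids <- ind$sample_id[ind$consanguineous]
  tot <- class5$total[match(consang_ids, class5$sample_id)]
  expect_true(all(tot / 2.88e9 >= 0.03))
})

test_that("loadings generation plants recoverable modules", {
  expect_error(generate_loadings(0, c("a", "b")), "n_components")
  gene_ids <- sprintf("G%03d", 1:60)
  sets <- list(`1` = gene_ids[1:10], `3` = gene_ids[21:30])
  L0 <- generate_loadings(4, gene_ids, sets, noise_sd = 0, seed = 1)
  got <- component_gene_sets(L0, top_n = 10)
  expect_setequal(got[["C1"]], sets[[1]])
  expect_setequal(got[["C3"]], sets[[2]])
  # profiles of two disjoint planted sets are anti-correlated
  L <- generate_loadings(4, gene_ids, sets, noise_sd = 0.05, seed = 2)
  cs <- component_gene_sets(L, top_n = 10)
  pa <- profile_counts(sets[[1]], cs)
  pb <- profile_counts(sets[[2]], cs)
  expect_lt(cor(pa$count, pb$count), 0)
  expect_identical(generate_loadings(4, gene_ids, sets, seed = 3),
                   generate_loadings(4, gene_ids, sets, seed = 3))
})

test_that("piRNA pair generation hits the requested mature fraction", {
  expect_error(generate_pirna_pair(0.5, 0.5, n_reads = 0), "positive")
  pair1 <- generate_pirna_pair(1, 0, n_reads = 5000, seed = 1)
  expect_equal(sum(pair1$case$count[pair1$case$length >= 32]), 0)
  expect_equal(sum(pair1$control$count[pair1$control$length < 32]), 0)
  expect_identical(attr(pair1$case, "spike_in_count"), 1000)

  pair <- generate_pirna_pair(0.5, 0.5, n_reads = 1e5, seed = 2)
  expect_lt(abs(mature_fraction(pair$case) - 0.5), 0.01)
  expect_true(all(pair$case$length >= 25 & pair$case$length <= 45))
})

test_that("tissue matrix planting round-trips through the classifier", {
  expect_error(
    generate_tissue_matrix(c(g = "group_enriched"), n_tissues = 7),
    "n_tissues")
  cls <- c("tissue_enriched", "group_enriched", "tissue_enhanced", "none")
  planted <- setNames(rep(cls, 25), sprintf("gene%03d", 1:100))
  mat <- generate_tissue_matrix(planted, seed = 1)
  expect_true(all(mat >= 0))
  got <- classify_tissue_specificity(mat)
  expect_identical(setNames(got$class, got$gene_id)[names(planted)], planted)
})
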