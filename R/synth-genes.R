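#' Generate a synthetic gene universe
#'
#' Builds a table of gene annotations of the kind that drives recessive
#' variant aggregation in an azoospermia exome study: chromosome, testis
#' expression class (Human-Protein-Atlas-style specificity), known
#' human/mouse infertility evidence, and normalized premeiotic single-cell
#' expression. Default proportions emulate the annotation landscape of the
#' human exome: roughly 12% of genes with elevated testis expression and a
#' premeiotic TPM distribution with a heavy upper tail.
#'
#' @param n_genes Number of genes (>= 1).
#' @param class_proportions Named numeric simplex over the testis classes
#'   `tissue_enriched`, `group_enriched`, `tissue_enhanced`, `none`;
#'   must sum to 1.
#' @param chrom_weights Named weights for chromosome assignment; defaults
#'   put ~96% of genes on autosomes 1..22, 3.5% on X and 0.5% on Y.
#' @param infertility_fraction Fraction of genes with known infertility
#'   evidence (human or mouse).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble of gene records: `gene_id`, `chromosome`,
#'   `is_lof_tolerant_context`, `testis_class`, `known_infertility`,
#'   `premeiotic_tpm`.
#' @examples
#' genes <- generate_gene_universe(500, seed = 1)
#' dplyr::count(genes, testis_class)
#' @export
generate_gene_universe <- function(n_genes,
                                   class_proportions = c(
                                     tissue_enriched = 0.05,
                                     group_enriched = 0.03,
                                     tissue_enhanced = 0.04,
                                     none = 0.88),
                                   chrom_weights = NULL,
                                   infertility_fraction = 0.02,
                                   seed = 1) {
  assert_count(n_genes, "n_genes")
  cls <- c("tissue_enriched", "group_enriched", "tissue_enhanced", "none")
  assert_that(is.numeric(class_proportions) &&
                setequal(names(class_proportions), cls) &&
                all(class_proportions >= 0) &&
                abs(sum(class_proportions) - 1) < 1e-8,
              "`class_proportions` must be a named simplex over the four testis classes")
  chroms <- c(as.character(1:22), "X", "Y")
  chrom_weights <- chrom_weights %||%
    setNames(c(rep(0.96 / 22, 22), 0.035, 0.005), chroms)
  assert_that(setequal(names(chrom_weights), chroms) &&
                all(chrom_weights >= 0) && sum(chrom_weights) > 0,
              "`chrom_weights` must be named non-negative weights over 1..22, X, Y")
  assert_scalar_num(infertility_fraction, "infertility_fraction", 0, 1)
  with_seed(seed, {
    tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chromosome = sample(chroms, n_genes, replace = TRUE,
                          prob = chrom_weights[chroms]),
      is_lof_tolerant_context = runif(n_genes) < 0.1,
      testis_class = sample(cls, n_genes, replace = TRUE,
                            prob = class_proportions[cls]),
      known_infertility = runif(n_genes) < infertility_fraction,
      premeiotic_tpm = stats::rlnorm(n_genes, meanlog = -1, sdlog = 1.5)
    )
  })
}

#' Generate a tissues-by-genes expression matrix with planted specificity
#'
#' Emits TPM profiles built so the rule-based classifier
#' ([classify_tissue_specificity()]) recovers each planted class:
#' `tissue_enriched` genes have one tissue at least 5-fold above all
#' others; `group_enriched` genes a group of 2-7 tissues 5-fold above the
#' rest; `tissue_enhanced` genes one tissue 5-fold above the all-tissue
#' mean but not 5-fold above every other tissue; `none` genes a flat
#' profile. A small multiplicative noise is applied; planted margins are
#' wide enough that it cannot flip a class.
#'
#' @param planted_classes Named character vector `gene_id -> class`.
#' @param n_tissues Number of tissues (default 37, a bulk-atlas-sized
#'   panel). At least 8 so that groups of 2-7 leave tissues outside the
#'   group; at least 14 when a `tissue_enhanced` gene is planted (the
#'   enhanced-but-not-enriched geometry needs that many tissues).
#' @param noise_cv Multiplicative log-normal noise coefficient (default
#'   0.02).
#' @param seed Integer seed.
#' @return A numeric matrix, tissues in rows (`T01`, ...), genes in
#'   columns.
#' @export
generate_tissue_matrix <- function(planted_classes, n_tissues = 37,
                                   noise_cv = 0.02, seed = 1) {
  cls <- c("tissue_enriched", "group_enriched", "tissue_enhanced", "none")
  assert_that(is.character(planted_classes) && length(planted_classes) >= 1 &&
                !is.null(names(planted_classes)) &&
                all(planted_classes %in% cls),
              "`planted_classes` must be a named character vector of valid classes")
  assert_count(n_tissues, "n_tissues", min = 3L)
  if (any(planted_classes == "group_enriched") && n_tissues < 8)
    rlang::abort("group_enriched planting needs n_tissues >= 8 (groups of 2-7)")
  if (any(planted_classes == "tissue_enhanced") && n_tissues < 14)
    rlang::abort("tissue_enhanced planting needs n_tissues >= 14")
  genes <- names(planted_classes)
  with_seed(seed, {
    base <- vapply(planted_classes, function(cl) {
      x <- switch(cl,
        tissue_enriched = {
          v <- rep(1, n_tissues); v[sample.int(n_tissues, 1)] <- 50; v
        },
        group_enriched = {
          k <- sample(2:min(7, n_tissues - 1), 1)
          v <- rep(2, n_tissues); v[sample.int(n_tissues, k)] <- 40; v
        },
        tissue_enhanced = {
          # one peak below 5x the mid tissues (not enriched, no 5x group of
          # <=7 because >=7 mids stay outside any group), but above 5x mean
          v <- rep(0.5, n_tissues)
          idx <- sample.int(n_tissues, 8)
          v[idx[1]] <- 45; v[idx[-1]] <- 10
          v
        },
        none = rep(5, n_tissues)
      )
      x
    }, numeric(n_tissues))
    noise <- matrix(stats::rlnorm(n_tissues * length(genes),
                                  meanlog = 0, sdlog = noise_cv),
                    nrow = n_tissues)
    mat <- base * noise
    dimnames(mat) <- list(sprintf("T%02d", seq_len(n_tissues)), genes)
    mat
  })
}
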