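#' Rule-based tissue-specificity classification
#'
#' Classifies each gene of a tissues-by-genes TPM matrix with the
#' fold-change rules used by bulk expression atlases:
#' `tissue_enriched` - expression in one tissue at least `fold` times
#' higher than in every other tissue; `group_enriched` - average TPM in a
#' group of `group_min`..`group_max` tissues at least `fold` times higher
#' than in every tissue outside the group; `tissue_enhanced` - TPM in at
#' least one tissue `fold` times higher than the mean TPM over all
#' tissues; otherwise `none`. Classes are assigned with precedence
#' enriched > group > enhanced, so they are mutually exclusive and
#' exhaustive, and all rules are ratio-based, hence invariant to global
#' rescaling of the matrix.
#'
#' The group search considers rank-contiguous top-k tissue sets only: the
#' best `fold`-separated group is always a prefix of the expression
#' ranking, so nothing is lost relative to exhaustive subset search.
#'
#' @param mat Numeric matrix, tissues in rows, genes in columns;
#'   non-negative TPM.
#' @param fold Fold-change threshold (> 1, default 5).
#' @param group_min,group_max Allowed group sizes (defaults 2 and 7).
#' @return A tibble with columns `gene_id`, `class`.
#' @examples
#' m <- generate_tissue_matrix(c(A = "tissue_enriched", B = "none"), seed = 1)
#' classify_tissue_specificity(m)
#' @export
classify_tissue_specificity <- function(mat, fold = 5, group_min = 2,
                                        group_max = 7) {
  assert_that(is.matrix(mat) && is.numeric(mat), "`mat` must be numeric")
  assert_that(all(mat >= 0), "negative TPM values are not allowed")
  assert_scalar_num(fold, "fold", 1, strict_lower = TRUE)
  assert_that(group_min >= 2 && group_min <= group_max,
              "need 2 <= group_min <= group_max")
  n_tis <- nrow(mat)
  assert_that(n_tis >= group_max + 1,
              "need more tissues than the largest group size")
  classes <- vapply(seq_len(ncol(mat)), function(j) {
    x <- sort(mat[, j], decreasing = TRUE)
    if (x[1] <= 0) return("none")
    if (x[1] >= fold * x[2]) return("tissue_enriched")
    for (k in group_min:group_max) {
      grp <- mean(x[1:k])
      if (grp > 0 && grp >= fold * x[k + 1]) return("group_enriched")
    }
    if (x[1] >= fold * mean(x)) return("tissue_enhanced")
    "none"
  }, character(1))
  tibble(gene_id = colnames(mat) %||% as.character(seq_len(ncol(mat))),
         class = classes)
}

#' Top-loading gene sets of decomposition components
#'
#' For each component of a components-by-genes loadings matrix, the `top_n`
#' genes by loading, taken from the requested side: `"combined"` ranks by
#' absolute loading, `"positive"` by loading, `"negative"` by negated
#' loading. Ties are broken deterministically by gene id.
#'
#' @param loadings Numeric matrix, components in rows, genes in columns
#'   (both named).
#' @param top_n Genes per component (default 250; must not exceed the gene
#'   count).
#' @param side `"combined"`, `"positive"` or `"negative"`.
#' @return A named list: component -> character vector of gene ids.
#' @export
component_gene_sets <- function(loadings, top_n = 250,
                                side = c("combined", "positive", "negative")) {
  side <- match.arg(side)
  assert_that(is.matrix(loadings) && is.numeric(loadings),
              "`loadings` must be a numeric matrix")
  assert_that(all(is.finite(loadings)), "loadings must be finite")
  assert_count(top_n, "top_n")
  assert_that(top_n <= ncol(loadings),
              "`top_n` cannot exceed the number of genes")
  gene_ids <- colnames(loadings) %||% as.character(seq_len(ncol(loadings)))
  comp_ids <- rownames(loadings) %||% as.character(seq_len(nrow(loadings)))
  sets <- lapply(seq_len(nrow(loadings)), function(i) {
    score <- switch(side,
      combined = abs(loadings[i, ]),
      positive = loadings[i, ],
      negative = -loadings[i, ])
    ord <- order(-score, gene_ids)
    gene_ids[ord[seq_len(top_n)]]
  })
  names(sets) <- comp_ids
  sets
}

#' Per-component counts of a query gene set
#'
#' Counts how many genes of a query set appear in each component's
#' top-loading gene set - the "profile" of the query set over the
#' decomposition, used to compare where different classes of disease genes
#' act during germ-cell development. Additive over disjoint query sets.
#'
#' @param query_genes Character vector of gene ids.
#' @param component_sets Named list from [component_gene_sets()].
#' @return A `component_profile` tibble with columns `component`, `count`.
#' @export
profile_counts <- function(query_genes, component_sets) {
  assert_that(is.list(component_sets) && length(component_sets) >= 1,
              "`component_sets` must be a non-empty list")
  out <- tibble(
    component = names(component_sets) %||%
      as.character(seq_along(component_sets)),
    count = vapply(component_sets, function(s)
      length(intersect(unique(query_genes), s)), integer(1),
      USE.NAMES = FALSE))
  class(out) <- c("component_profile", class(out))
  out
}

#' Pearson-Filon test for two overlapping dependent correlations
#'
#' Tests whether two correlations sharing one variable differ:
#' `r_jk = cor(j, k)` versus `r_jh = cor(j, h)` measured on the same `n`
#' observations, with `r_kh = cor(k, h)` accounting for the dependence.
#' Computed on Fisher-transformed correlations with the Pearson-Filon
#' covariance term (the "ZPF" form, well calibrated at moderate n):
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{(n-3) / (2 - 2c)}}
#' where \eqn{c} is the Pearson-Filon covariance of the two correlations
#' scaled by \eqn{(1-r_{jk}^2)(1-r_{jh}^2)}.
#'
#' @param r_jk,r_jh The two correlations sharing variable j, in (-1, 1).
#' @param r_kh Correlation of the non-shared pair, in (-1, 1).
#' @param n Sample size (>= 4).
#' @return A tibble with columns `z`, `p_two_sided`.
#' @examples
#' pearson_filon_test(0.54, 0.087, 0.2, n = 70)
#' @export
pearson_filon_test <- function(r_jk, r_jh, r_kh, n) {
  for (r in c(r_jk, r_jh, r_kh))
    assert_scalar_num(r, "correlation", -1, 1)
  if (abs(r_jk) == 1 || abs(r_jh) == 1)
    rlang::abort("|r| = 1: Fisher transform undefined")
  assert_count(n, "n", min = 4L)
  if (r_jk == r_jh) return(tibble(z = 0, p_two_sided = 1))
  k <- r_kh * (1 - r_jk^2 - r_jh^2) -
    (r_jk * r_jh / 2) * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  c_z <- k / ((1 - r_jk^2) * (1 - r_jh^2))
  denom <- 2 - 2 * c_z
  z <- if (denom <= 0) sign(atanh(r_jk) - atanh(r_jh)) * Inf
       else (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / denom)
  tibble(z = z, p_two_sided = 2 * pnorm(-abs(z)))
}

#' Hypergeometric enrichment of a query set in a component gene set
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a query gene set and a component's top-loading set,
#' drawn from a universe of `universe_size` genes.
#'
#' @param query_genes Character vector (within the universe).
#' @param component_set Character vector: the component's gene set.
#' @param universe_size Total number of genes in the universe.
#' @return A tibble with `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p`.
#' @export
component_enrichment <- function(query_genes, component_set, universe_size) {
  query_genes <- unique(query_genes)
  component_set <- unique(component_set)
  assert_count(universe_size, "universe_size")
  assert_that(length(query_genes) <= universe_size &&
                length(component_set) <= universe_size,
              "sets cannot exceed the universe")
  ov <- length(intersect(query_genes, component_set))
  p <- phyper(ov - 1, length(component_set),
              universe_size - length(component_set),
              length(query_genes), lower.tail = FALSE)
  tibble(overlap = ov, query_size = length(query_genes),
         set_size = length(component_set), universe_size = universe_size,
         p = min(p, 1))
}

#' Compare two component profiles against a shared reference profile
#'
#' Pearson correlations of profiles `a` and `b` with a reference profile,
#' their direct correlation, and - when a reference is supplied - the
#' Pearson-Filon test of whether `a` and `b` correlate differently with
#' the reference (the three correlations share the reference variable and
#' are measured over the same components).
#'
#' @param profile_a,profile_b,profile_ref Equal-length numeric vectors of
#'   per-component counts (`component_profile` tibbles are accepted).
#' @return A tibble with `r_a_ref`, `r_b_ref`, `r_ab`, `z`, `p_two_sided`
#'   (test columns `NA` when `profile_ref` is `NULL`).
#' @export
profile_comparison <- function(profile_a, profile_b, profile_ref = NULL) {
  as_vec <- function(x) {
    if (is.data.frame(x)) x$count else as.numeric(x)
  }
  a <- as_vec(profile_a); b <- as_vec(profile_b)
  assert_that(length(a) == length(b), "profiles must have equal length")
  if (sd(a) == 0 || sd(b) == 0) {
    rlang::warn("zero-variance profile; correlation undefined")
    return(tibble(r_a_ref = NA_real_, r_b_ref = NA_real_, r_ab = NA_real_,
                  z = NA_real_, p_two_sided = NA_real_))
  }
  r_ab <- cor(a, b)
  if (is.null(profile_ref))
    return(tibble(r_a_ref = NA_real_, r_b_ref = NA_real_, r_ab = r_ab,
                  z = NA_real_, p_two_sided = NA_real_))
  ref <- as_vec(profile_ref)
  assert_that(length(ref) == length(a), "profiles must have equal length")
  if (sd(ref) == 0) {
    rlang::warn("zero-variance reference profile; correlation undefined")
    return(tibble(r_a_ref = NA_real_, r_b_ref = NA_real_, r_ab = r_ab,
                  z = NA_real_, p_two_sided = NA_real_))
  }
  r_a <- cor(a, ref); r_b <- cor(b, ref)
  pf <- pearson_filon_test(r_a, r_b, r_ab, n = length(a))
  tibble(r_a_ref = r_a, r_b_ref = r_b, r_ab = r_ab,
         z = pf$z, p_two_sided = pf$p_two_sided)
}
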