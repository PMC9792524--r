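#' Generate a components-by-genes loadings matrix with planted modules
#'
#' Emulates the gene-loadings output of a sparse decomposition of
#' single-cell data: each planted gene module receives high-magnitude
#' loadings on its component, everything else is zero-mean Gaussian noise.
#'
#' @param n_components Number of latent components (>= 1).
#' @param gene_ids Character vector: the gene universe (matrix columns).
#' @param planted_sets Named list mapping component index (as character or
#'   integer-like name, e.g. `"3"`) to a character vector of planted genes;
#'   all planted genes must be in `gene_ids`.
#' @param signal_loading Mean magnitude of planted loadings (default 5).
#' @param noise_sd Standard deviation of background loadings (0 allowed).
#' @param seed Integer seed.
#' @return A numeric matrix, components in rows (`C1`, ...), genes in
#'   columns.
#' @examples
#' L <- generate_loadings(5, sprintf("G%03d", 1:50),
#'                        list(`2` = sprintf("G%03d", 1:10)), seed = 1)
#' dim(L)
#' @export
generate_loadings <- function(n_components, gene_ids, planted_sets = list(),
                              signal_loading = 5, noise_sd = 0.1, seed = 1) {
  assert_count(n_components, "n_components")
  assert_that(is.character(gene_ids) && length(gene_ids) >= 1 &&
                !anyDuplicated(gene_ids),
              "`gene_ids` must be unique gene identifiers")
  assert_scalar_num(noise_sd, "noise_sd", 0)
  comp_idx <- suppressWarnings(as.integer(names(planted_sets)))
  assert_that(length(planted_sets) == 0 ||
                (!anyNA(comp_idx) && all(comp_idx >= 1) &&
                   all(comp_idx <= n_components)),
              "`planted_sets` names must be component indices in range")
  assert_that(all(unlist(planted_sets) %in% gene_ids),
              "planted genes must belong to `gene_ids`")
  with_seed(seed, {
    mat <- matrix(rnorm(n_components * length(gene_ids), 0, noise_sd),
                  nrow = n_components,
                  dimnames = list(sprintf("C%d", seq_len(n_components)),
                                  gene_ids))
    for (j in seq_along(planted_sets)) {
      k <- comp_idx[j]
      gs <- planted_sets[[j]]
      signs <- sample(c(-1, 1), length(gs), replace = TRUE)
      mat[k, gs] <- signs * (signal_loading + rnorm(length(gs), 0, noise_sd))
    }
    mat
  })
}
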