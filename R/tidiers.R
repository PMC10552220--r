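## broom-style accessors for projection results.

#' Tidy a projection result
#'
#' @param x An `mc_projection` from [project_query()].
#' @param what Which table to return: `"metacells"` (per-metacell QC, the
#'   default), `"genes"` (per-gene QC), `"weights"` (long sparse mixture
#'   weights with atlas types), or `"skewed"` (per-type skewed genes).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mc_projection
#' @export
tidy.mc_projection <- function(x, what = c("metacells", "genes",
                                           "weights", "skewed"), ...) {
  what <- match.arg(what)
  switch(
    what,
    metacells = x$metacells,
    genes = x$gene_qc,
    weights = {
      idx <- which(x$weights > 0, arr.ind = TRUE)
      tibble::tibble(
        metacell = x$query_metacells[idx[, 1]],
        atlas_metacell = x$atlas_metacells[idx[, 2]],
        atlas_type = x$atlas_types[idx[, 2]],
        weight = x$weights[idx]
      ) |>
        dplyr::arrange(.data$metacell, dplyr::desc(.data$weight))
    },
    skewed = tibble::tibble(
      type = rep(names(x$skew_sets),
                 vapply(x$skew_sets, length, integer(1))),
      gene = x$genes[unlist(x$skew_sets, use.names = FALSE) %||% integer()]
    )
  )
}

#' One-row summary of a projection result
#'
#' @param x An `mc_projection`.
#' @param ... Unused.
#' @return A one-row tibble with counts of query metacells, similar /
#'   unassigned / composite metacells, the median fitted-gene fraction and
#'   median r2, and the number of corrected genes.
#' @method glance mc_projection
#' @export
glance.mc_projection <- function(x, ...) {
  mc <- x$metacells
  tibble::tibble(
    n_query = nrow(mc),
    n_atlas = length(x$atlas_metacells),
    n_genes = length(x$genes),
    n_feature = x$n_feature_common,
    n_similar = sum(mc$similar),
    n_unassigned = sum(mc$unassigned),
    n_composite = sum(mc$composite_type != ""),
    median_fitted_fraction = stats::median(mc$n_fitted) /
      max(x$n_feature_common, 1L),
    median_r2 = stats::median(mc$r2),
    n_corrected_genes = sum(x$gene_qc$correction_factor != 1)
  )
}
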