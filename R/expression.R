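## Log expression matrices over the common gene space.

#' Log2 expression from UMI counts
#'
#' Converts a metacell-by-gene count matrix over the common gene space into
#' expression fractions and regularized log2 expression,
#' `e = log2(epsilon + u / N)`, where `N` is the per-metacell total UMI
#' count summed over the *common* genes only.
#'
#' @param umis Count matrix restricted to the common gene space
#'   (metacells x genes).
#' @param epsilon Regularization added to fractions before log2
#'   (default `1e-5`).
#' @return A list with `e` (log2 expression), `fractions` (u / N) and
#'   `totals` (per-metacell N over the common genes).
#' @export
#' @examples
#' u <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("a", "b"), c("g1", "g2")))
#' compute_log_expression(u)$e
compute_log_expression <- function(umis, epsilon = 1e-5) {
  totals <- rowSums(umis)
  if (any(totals == 0)) {
    abort(paste0(
      "metacells with zero UMIs over the common genes: ",
      paste(head(rownames(umis)[totals == 0], 5L), collapse = ", ")
    ))
  }
  fractions <- umis / totals
  list(
    e = log2(epsilon + fractions),
    fractions = fractions,
    totals = totals
  )
}

## Pearson correlation between the rows of two matrices, computed over a
## gene mask; zero-variance profiles yield 0 rather than NA.
cor_rows <- function(x, y, mask = NULL) {
  if (!is.null(mask)) {
    x <- x[, mask, drop = FALSE]
    y <- y[, mask, drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(t(x), t(y)))
  r[!is.finite(r)] <- 0
  r
}

#' Query-to-atlas correlation matrix
#'
#' Pearson correlation between every query and atlas metacell pair,
#' computed over the genes selected by `gene_mask`. Pairs involving a
#' zero-variance profile get correlation 0 (never `NA`), so degenerate
#' profiles can never win an anchor unless nothing else exists.
#'
#' @param e_query,e_atlas Log2 expression matrices (metacells x genes) over
#'   the same common gene space.
#' @param gene_mask Logical vector over the common genes; must select at
#'   least two genes.
#' @return A query-by-atlas correlation matrix.
#' @export
correlate_profiles <- function(e_query, e_atlas, gene_mask = NULL) {
  if (is.null(gene_mask)) {
    gene_mask <- rep(TRUE, ncol(e_atlas))
  }
  if (sum(gene_mask) < 2L) {
    abort("correlate_profiles: the gene mask must select at least 2 genes")
  }
  cor_rows(e_query, e_atlas, gene_mask)
}
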