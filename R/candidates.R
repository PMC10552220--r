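## Anchor distances and candidate-set selection.

## Chebyshev (max absolute log2 difference) distance of every atlas
## metacell to the anchor, over the masked genes. The anchor has d = 0.
anchor_distances <- function(anchor, e_atlas, gene_mask) {
  a <- e_atlas[, gene_mask, drop = FALSE]
  ref <- matrix(a[anchor, ], nrow(a), ncol(a), byrow = TRUE)
  d <- abs(a - ref)
  apply(d, 1L, max)
}

#' Select candidate atlas metacells around an anchor
#'
#' Takes the `n_closest_candidates` atlas metacells with the smallest
#' max-absolute log2 expression distance to the anchor (the anchor itself,
#' at distance 0, is always among them), and extends the set with up to
#' `n_extra_candidates` additional metacells whose distance is strictly
#' below `max_candidate_distance`. Members are returned in increasing
#' distance order; distance ties are broken by the lower atlas index.
#'
#' @param anchor Atlas metacell index (row of `e_atlas`).
#' @param e_atlas Atlas log2 expression matrix (metacells x genes).
#' @param gene_mask Logical vector over the common genes.
#' @param n_closest,n_extra,max_distance The selection rule parameters
#'   (defaults 10, 40 and 2 log2 units).
#' @return A list of class `mc_candidates` with `anchor`, `members`
#'   (ordered atlas indices) and `distances` (per-atlas-metacell distance
#'   to the anchor).
#' @export
select_candidates <- function(anchor, e_atlas, gene_mask = NULL,
                              n_closest = 10L, n_extra = 40L,
                              max_distance = 2) {
  n <- nrow(e_atlas)
  stopifnot(n >= 1L, anchor >= 1L, anchor <= n)
  if (is.null(gene_mask)) {
    gene_mask <- rep(TRUE, ncol(e_atlas))
  }
  d <- anchor_distances(anchor, e_atlas, gene_mask)
  ord <- order(d, seq_len(n))
  closest <- ord[seq_len(min(n_closest, n))]
  rest <- ord[-seq_len(min(n_closest, n))]
  extra <- rest[d[rest] < max_distance]
  extra <- extra[seq_len(min(n_extra, length(extra)))]
  structure(
    list(
      anchor = anchor,
      members = c(closest, extra),
      distances = d
    ),
    class = "mc_candidates"
  )
}
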