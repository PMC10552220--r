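## One seeding-and-mixture round over all query metacells.

project_one <- function(eq_vec, e_atlas, fr_atlas, gene_mask, cfg) {
  if (!is.null(gene_mask) && sum(gene_mask) < 2L) {
    # a fully filtered mask cannot drive a fit; fall back to all common
    # genes (the QC bookkeeping still records the empty fitted mask, so
    # such metacells can never be called similar)
    amp_log(cfg, "fitted mask has < 2 genes; fitting over all common genes")
    gene_mask <- NULL
  }
  cors <- drop(cor_rows(matrix(eq_vec, 1L), e_atlas, gene_mask))
  anchor <- which.max(cors) # ties: lowest atlas index wins
  cand <- select_candidates(
    anchor, e_atlas, gene_mask,
    n_closest = cfg$n_closest_candidates,
    n_extra = cfg$n_extra_candidates,
    max_distance = cfg$max_candidate_distance
  )
  w <- solve_mixture_weights(
    eq_vec, e_atlas, cand,
    gene_mask = gene_mask,
    min_weight = cfg$min_weight,
    ridge = cfg$solver_ridge
  )
  # the projected distribution is the convex mixture of the candidate
  # fraction vectors (weights are solved on log expression, above)
  members <- as.integer(names(w))
  fr <- drop(w %*% fr_atlas[members, , drop = FALSE])
  list(
    anchor = anchor,
    candidates = cand,
    weights = w,
    e = log2(cfg$epsilon + fr),
    fractions = fr
  )
}

#' Preliminary projection of every query metacell
#'
#' For each query metacell: finds the anchor (most correlated atlas
#' metacell), extends it to a candidate set, solves the simplex-constrained
#' least-squares mixture over the masked genes, and computes the projected
#' expression over all common genes. The computation is deterministic.
#'
#' @param e_query Query log2 expression matrix (metacells x genes, common
#'   gene space).
#' @param e_atlas Atlas log2 expression matrix over the same genes.
#' @param gene_mask Either a single logical vector over the common genes,
#'   or a list of such vectors, one per query metacell (used when each
#'   metacell is fitted with its own type's gene mask).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_projection_state` with `weights` (dense
#'   query-by-atlas weight matrix), `e_projected`, `fractions_projected`,
#'   `anchors`, and the per-metacell `candidates` list.
#' @export
project_all <- function(e_query, e_atlas, gene_mask = NULL, config = list()) {
  cfg <- if (identical(names(config), names(proj_defaults()))) {
    config
  } else {
    proj_config(config)
  }
  nq <- nrow(e_query)
  na <- nrow(e_atlas)
  masks <- if (is.list(gene_mask)) gene_mask else rep(list(gene_mask), nq)
  stopifnot(length(masks) == nq)
  fr_atlas <- pmax(2^e_atlas - cfg$epsilon, 0)
  fits <- purrr::map(seq_len(nq), function(i) {
    project_one(e_query[i, ], e_atlas, fr_atlas, masks[[i]], cfg)
  })
  W <- matrix(0, nq, na, dimnames = list(rownames(e_query), rownames(e_atlas)))
  for (i in seq_len(nq)) {
    W[i, as.integer(names(fits[[i]]$weights))] <- fits[[i]]$weights
  }
  e_p <- do.call(rbind, purrr::map(fits, "e"))
  fr_p <- do.call(rbind, purrr::map(fits, "fractions"))
  dimnames(e_p) <- dimnames(fr_p) <- dimnames(e_query)
  structure(
    list(
      weights = W,
      e_projected = e_p,
      fractions_projected = fr_p,
      anchors = vapply(fits, function(f) f$anchor, integer(1)),
      candidates = purrr::map(fits, "candidates")
    ),
    class = "mc_projection_state"
  )
}
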