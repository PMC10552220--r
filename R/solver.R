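## Simplex-constrained least squares: the mixture-weight solver.

## Exact QP solve of min ||A w - b||^2 s.t. sum(w) = 1, w >= 0, where A is
## genes x candidates. A tiny ridge keeps the Gram matrix positive
## definite when candidates are (nearly) collinear.
simplex_lsq <- function(A, b, ridge = 1e-10) {
  k <- ncol(A)
  if (k == 1L) {
    return(1)
  }
  G <- crossprod(A)
  G <- G + diag(ridge * max(diag(G), 1), k)
  d <- drop(crossprod(A, b))
  Amat <- cbind(rep(1, k), diag(k))
  sol <- quadprog::solve.QP(G, d, Amat, bvec = c(1, rep(0, k)), meq = 1L)
  sol$solution
}

#' Solve for mixture weights on the probability simplex
#'
#' Finds the convex combination of candidate atlas profiles closest (in L2,
#' over the masked genes) to a query log2 expression vector:
#' minimize `||e_query - sum_k w_k e_atlas[k]||` subject to `sum(w) = 1`,
#' `w >= 0`. Weights below `min_weight` are removed and the remainder
#' renormalized to sum to 1. If the quadratic program fails, the anchor
#' alone gets weight 1 (with a warning).
#'
#' @param query_vec Query log2 expression vector over the common genes.
#' @param e_atlas Atlas log2 expression matrix (metacells x genes).
#' @param candidates An `mc_candidates` object (or a list with `members`
#'   and `anchor`).
#' @param gene_mask Logical vector over the common genes (at least one
#'   gene); the objective is computed over these genes only.
#' @param min_weight Weights smaller than this are dropped (default `1e-5`).
#' @param ridge Diagonal stabilizer for the Gram matrix (default `1e-10`).
#' @return A named numeric vector of weights over `candidates$members`
#'   (names are atlas metacell indices as stored in `members`); entries are
#'   `>= min_weight` and sum to 1 within 1e-9.
#' @export
solve_mixture_weights <- function(query_vec, e_atlas, candidates,
                                  gene_mask = NULL, min_weight = 1e-5,
                                  ridge = 1e-10) {
  members <- candidates$members
  stopifnot(length(members) >= 1L)
  if (is.null(gene_mask)) {
    gene_mask <- rep(TRUE, ncol(e_atlas))
  }
  if (sum(gene_mask) < 1L) {
    abort("solve_mixture_weights: the gene mask must select at least 1 gene")
  }
  A <- t(e_atlas[members, gene_mask, drop = FALSE])
  b <- query_vec[gene_mask]
  w <- tryCatch(
    simplex_lsq(A, b, ridge = ridge),
    error = function(e) {
      warn(paste0(
        "mixture solver failed (", conditionMessage(e),
        "); falling back to anchor-only weights"
      ))
      as.numeric(members == candidates$anchor)
    }
  )
  # negative round-off is clipped before the cleanup threshold
  w[w < 0] <- 0
  w[w < min_weight] <- 0
  if (sum(w) == 0) {
    w <- as.numeric(members == candidates$anchor)
  }
  w <- w / sum(w)
  names(w) <- as.character(members)
  w
}

#' Project expression from mixture weights
#'
#' The projected log2 expression is the weighted average of the candidate
#' atlas log2 expression vectors over *all* common genes (not only the
#' fitted ones), so that filtered genes can still be inspected downstream.
#' Linear-scale projected fractions are recovered by inverting the log
#' transform and clipping at zero.
#'
#' @param weights Named weight vector as returned by
#'   [solve_mixture_weights()] (names are atlas row indices).
#' @param e_atlas Atlas log2 expression matrix (metacells x genes).
#' @param epsilon Regularization used when the log expression was computed.
#' @return A list with `e` (projected log2 expression vector) and
#'   `fractions` (linear-scale projected fractions, `pmax(2^e - epsilon, 0)`).
#' @export
project_expression <- function(weights, e_atlas, epsilon = 1e-5) {
  members <- as.integer(names(weights))
  e <- drop(weights %*% e_atlas[members, , drop = FALSE])
  list(e = e, fractions = pmax(2^e - epsilon, 0))
}
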