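## Per-metacell and per-gene QC.

#' Squared correlation between observed and projected expression
#'
#' Per-metacell squared Pearson correlation between the (corrected) query
#' log2 expression and its projection, over each metacell's fitted genes.
#' Metacells with fewer than two fitted genes, or a zero-variance side,
#' get `r2 = 0`.
#'
#' @param e_query,e_projected Log2 expression matrices
#'   (metacells x genes).
#' @param fitted Either one logical vector over genes or a list of
#'   per-metacell logical masks.
#' @return Numeric vector of per-metacell `r2` values.
#' @export
compute_r2 <- function(e_query, e_projected, fitted = NULL) {
  nq <- nrow(e_query)
  if (is.null(fitted)) fitted <- rep(TRUE, ncol(e_query))
  masks <- if (is.list(fitted)) fitted else rep(list(fitted), nq)
  vapply(seq_len(nq), function(i) {
    m <- masks[[i]]
    if (sum(m) < 2L) {
      return(0)
    }
    r <- suppressWarnings(stats::cor(e_query[i, m], e_projected[i, m]))
    if (!is.finite(r)) 0 else r^2
  }, numeric(1))
}

## The similar mask is a pure function of the QC ledger: not unassigned,
## and fitted at least a third of the atlas feature genes present in the
## common space.
similar_mask <- function(misfit_count, essential_fraction, n_fitted,
                         n_feature, cfg) {
  misfit_count <= cfg$max_misfit &
    essential_fraction < cfg$max_essential_fraction &
    n_fitted >= n_feature / 3
}

#' Recompute misfit QC at a different fold threshold
#'
#' Re-derives the misfit indicators, misfit counts, essential fractions,
#' unassigned flags and the similar mask from the stored per-gene fold
#' deviations, without re-running the projection. Composite acceptance is
#' not revisited. Running it at the original thresholds reproduces the
#' original QC exactly.
#'
#' @param result An `mc_projection` from [project_query()].
#' @param max_lfold New log2 fold threshold (default: the stored one).
#' @param min_umis New UMI-depth gate (default: the stored one).
#' @return The updated `mc_projection`.
#' @export
recompute_misfits <- function(result, max_lfold = NULL, min_umis = NULL) {
  stopifnot(inherits(result, "mc_projection"))
  cfg <- result$config
  cfg$max_lfold <- max_lfold %||% cfg$max_lfold
  cfg$min_umis <- min_umis %||% cfg$min_umis
  delta <- abs(result$lfold) > cfg$max_lfold & result$umi_sum >= cfg$min_umis
  delta[, result$exempt] <- FALSE
  mc <- result$metacells
  n_feature <- result$n_feature_common
  for (i in seq_len(nrow(mc))) {
    t1 <- mc$projected_type[[i]]
    t2 <- mc$composite_type[[i]]
    skew_idx <- result$skew_sets[[t1]] %||% integer()
    ess_idx <- result$essential_idx[[t1]] %||% integer()
    fitted <- result$masks_by_type[[t1]]
    if (!is.na(t2) && t2 != "") {
      skew_idx <- union(skew_idx, result$skew_sets[[t2]] %||% integer())
      ess_idx <- union(ess_idx, result$essential_idx[[t2]] %||% integer())
      fitted <- fitted & result$masks_by_type[[t2]]
    }
    row <- delta[i, ]
    row[skew_idx] <- FALSE
    delta[i, ] <- row
    st <- misfit_stats(row, fitted, ess_idx)
    mc$misfit_count[[i]] <- st$misfit
    mc$misfit_essential_fraction[[i]] <- st$essential_fraction
  }
  mc$unassigned <- mc$misfit_count > cfg$max_misfit |
    mc$misfit_essential_fraction >= cfg$max_essential_fraction
  mc$similar <- similar_mask(
    mc$misfit_count, mc$misfit_essential_fraction, mc$n_fitted,
    n_feature, cfg
  )
  result$delta <- delta
  result$metacells <- mc
  result$config <- cfg
  result
}

#' @export
print.mc_projection <- function(x, ...) {
  mc <- x$metacells
  cat(
    "metacell projection: ", nrow(mc), " query metacells onto ",
    length(x$atlas_metacells), " atlas metacells (",
    length(x$genes), " common genes)\n",
    "  similar: ", sum(mc$similar),
    ", unassigned: ", sum(mc$unassigned),
    ", composite: ", sum(!is.na(mc$composite_type) & mc$composite_type != ""),
    ", median r2: ", signif(stats::median(mc$r2), 3), "\n",
    sep = ""
  )
  invisible(x)
}
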