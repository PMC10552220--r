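## Unassigned metacells and two-region (doublet-like) composite fits.

## Zero the misfit indicators of each type's skewed genes for the
## metacells assigned to that type.
zero_type_skew <- function(delta, types, skew_sets) {
  for (t in names(skew_sets)) {
    idx <- skew_sets[[t]]
    if (length(idx) > 0L) {
      delta[types == t, idx] <- FALSE
    }
  }
  delta
}

## Misfit count over a fitted mask and essential-gene misfit fraction for
## one metacell row of a (skew-zeroed) delta matrix.
misfit_stats <- function(delta_row, fitted_mask, essential_idx) {
  n_misfit <- sum(delta_row[fitted_mask])
  ess_frac <- if (length(essential_idx) == 0L) {
    0
  } else {
    mean(delta_row[essential_idx])
  }
  list(misfit = n_misfit, essential_fraction = ess_frac)
}

#' Flag unassigned query metacells
#'
#' After zeroing the misfit indicators of type-skewed genes for metacells
#' of the respective type, a metacell is unassigned when it has strictly
#' more than `max_misfit` misfit fitted genes, or when at least
#' `max_essential_fraction` of its assigned type's essential genes are
#' misfit. A type with no essential genes contributes fraction 0.
#'
#' @param deviation An `mc_deviation` from [compute_deviation()].
#' @param types Character vector of assigned types per query metacell.
#' @param skew_sets Named list (type -> gene indices) of type-skewed genes.
#' @param masks_by_type Named list (type -> logical fitted mask).
#' @param essential_idx Named list (type -> indices of the type's
#'   essential genes within the common gene space).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A tibble with one row per metacell: `misfit_count`,
#'   `misfit_essential_fraction`, `unassigned`.
#' @export
flag_unassigned <- function(deviation, types, skew_sets, masks_by_type,
                            essential_idx, config = list()) {
  cfg <- proj_config(config)
  delta <- zero_type_skew(deviation$delta, types, skew_sets)
  rows <- purrr::map(seq_along(types), function(i) {
    t <- types[[i]]
    st <- misfit_stats(delta[i, ], masks_by_type[[t]],
                       essential_idx[[t]] %||% integer())
    tibble::tibble(
      misfit_count = st$misfit,
      misfit_essential_fraction = st$essential_fraction
    )
  })
  out <- dplyr::bind_rows(rows)
  out$unassigned <- out$misfit_count > cfg$max_misfit |
    out$misfit_essential_fraction >= cfg$max_essential_fraction
  out
}

#' Candidate atlas metacells for the residual of a projection
#'
#' Subtracts the projected expression from both the query vector and every
#' atlas profile, seeds a second anchor on the correlation between the
#' residual distributions, and extends it with the usual candidate rule.
#' (Anchor-to-metacell distances are unchanged by subtracting a common
#' vector, so they are computed on the original atlas expressions.)
#' Returns `NULL` when the residual has (near-)zero variance over the
#' masked genes, in which case a composite attempt is abandoned.
#'
#' @param query_vec Query log2 expression vector.
#' @param projected_vec Its current projected log2 expression vector.
#' @param e_atlas Atlas log2 expression matrix.
#' @param gene_mask Logical vector over the common genes.
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return An `mc_candidates` object, or `NULL` for a degenerate residual.
#' @export
residual_candidates <- function(query_vec, projected_vec, e_atlas,
                                gene_mask = NULL, config = list()) {
  cfg <- proj_config(config)
  if (is.null(gene_mask)) gene_mask <- rep(TRUE, ncol(e_atlas))
  rq <- (query_vec - projected_vec)[gene_mask]
  if (stats::sd(rq) < 1e-12) {
    amp_log(cfg, "composite: residual has zero variance; attempt abandoned")
    return(NULL)
  }
  ra <- sweep(e_atlas[, gene_mask, drop = FALSE], 2L, projected_vec[gene_mask])
  cors <- drop(cor_rows(matrix(rq, 1L), ra))
  anchor <- which.max(cors)
  select_candidates(
    anchor, e_atlas, gene_mask,
    n_closest = cfg$n_closest_candidates,
    n_extra = cfg$n_extra_candidates,
    max_distance = cfg$max_candidate_distance
  )
}

## Dominant type within a subset of weights (same lexicographic
## tie-breaking as assign_types); NULL when the subset has zero weight.
dominant_type <- function(weights, members, atlas_types) {
  idx <- members[weights[as.character(members)] > 0]
  if (length(idx) == 0L) {
    return(NULL)
  }
  sums <- tapply(weights[as.character(idx)], atlas_types[idx], sum)
  sums <- sums[order(names(sums))]
  names(sums)[which.max(sums)]
}

#' Fit a query metacell as a two-region composite
#'
#' Solves the simplex-constrained least squares over the union of the
#' primary and secondary (residual) candidate sets, working with the
#' original (not residual) expression values. The fit is accepted when,
#' with the type-skewed genes of both involved types zeroed, the metacell
#' has at most `max_misfit` misfit genes over the intersection of the two
#' types' fitted masks and strictly fewer than `max_essential_fraction`
#' misfit essential genes of the two types combined.
#'
#' @param query_vec Query log2 expression vector over the common genes.
#' @param primary,secondary `mc_candidates` objects for the two regions.
#' @param e_atlas Atlas log2 expression matrix.
#' @param gene_mask Logical fitted-gene mask used for the refit.
#' @param fr_query_vec Corrected query fraction vector for the metacell.
#' @param total Query metacell total UMIs over the common genes.
#' @param atlas_types Character vector of atlas metacell types.
#' @param skew_sets,masks_by_type,essential_idx Per-type bookkeeping as in
#'   [flag_unassigned()].
#' @param exempt Logical vector over genes (noisy or lateral).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_composite` with the union `weights`, the
#'   recomputed `e`, `fractions` and `delta`, `primary_type`,
#'   `secondary_type`, `misfit_count`, `misfit_essential_fraction`,
#'   `fitted_mask` and the `accepted` flag; or `NULL` when no distinct
#'   secondary region exists.
#' @export
fit_composite <- function(query_vec, primary, secondary, e_atlas,
                          gene_mask, fr_query_vec, total, atlas_types,
                          skew_sets, masks_by_type, essential_idx,
                          exempt = NULL, config = list()) {
  cfg <- proj_config(config)
  members <- c(primary$members, setdiff(secondary$members, primary$members))
  cand <- structure(
    list(anchor = primary$anchor, members = members,
         distances = primary$distances),
    class = "mc_candidates"
  )
  w <- solve_mixture_weights(
    query_vec, e_atlas, cand,
    gene_mask = gene_mask,
    min_weight = cfg$min_weight,
    ridge = cfg$solver_ridge
  )
  members_used <- as.integer(names(w))
  fr_atlas <- pmax(2^e_atlas - cfg$epsilon, 0)
  fr_proj <- drop(w %*% fr_atlas[members_used, , drop = FALSE])
  proj <- list(e = log2(cfg$epsilon + fr_proj), fractions = fr_proj)
  w_full <- setNames(rep(0, length(members)), as.character(members))
  w_full[names(w)] <- w
  primary_type <- dominant_type(w_full, primary$members, atlas_types)
  secondary_type <- dominant_type(
    w_full, setdiff(secondary$members, primary$members), atlas_types
  )
  dev <- compute_deviation(
    matrix(fr_query_vec, 1L), matrix(proj$fractions, 1L), total,
    exempt = exempt, config = cfg
  )
  delta <- drop(dev$delta)
  if (is.null(primary_type) || is.null(secondary_type) ||
      identical(secondary_type, primary_type)) {
    # no distinct second region carries weight: not a composite
    return(NULL)
  }
  skew_union <- union(skew_sets[[primary_type]] %||% integer(),
                      skew_sets[[secondary_type]] %||% integer())
  delta[skew_union] <- FALSE
  fitted_mask <- masks_by_type[[primary_type]] &
    masks_by_type[[secondary_type]]
  ess <- union(essential_idx[[primary_type]] %||% integer(),
               essential_idx[[secondary_type]] %||% integer())
  st <- misfit_stats(delta, fitted_mask, ess)
  accepted <- st$misfit <= cfg$max_misfit &&
    st$essential_fraction < cfg$max_essential_fraction
  structure(
    list(
      weights = w,
      members = members,
      e = proj$e,
      fractions = proj$fractions,
      delta = delta,
      primary_type = primary_type,
      secondary_type = secondary_type,
      misfit_count = st$misfit,
      misfit_essential_fraction = st$essential_fraction,
      fitted_mask = fitted_mask,
      accepted = accepted
    ),
    class = "mc_composite"
  )
}
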