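#' Default projection parameters
#'
#' All tunable parameters of the projection pipeline with their default
#' values. Every entry can be overridden by passing a named list to
#' [project_query()] (or individual arguments to the lower-level
#' functions); unknown keys are rejected.
#'
#' @details
#' * `epsilon` -- regularization added to expression fractions before
#'   taking log2 (default `1e-5`).
#' * `correct_genes` -- whether to infer and apply per-gene multiplicative
#'   technology corrections (default `FALSE`).
#' * `correction_min_fit` -- minimum query/projection correlation for a
#'   gene to be eligible for correction (default `0.8`).
#' * `correction_min_factor` -- minimum magnitude of the correction:
#'   a gene is only corrected when `abs(log(cf)) > log(correction_min_factor)`
#'   (default `1.15`).
#' * `correction_max_rounds` -- maximum correction/re-projection rounds
#'   (default `3`).
#' * `range_quantiles` -- quantiles bounding the per-gene expression range
#'   (default `c(0.02, 0.98)`).
#' * `range_min_shared` -- a gene is dropped when the shared query/projection
#'   range is strictly less than this fraction of the query range
#'   (default `0.5`).
#' * `max_lfold` -- log2 fold deviation above which a gene is a misfit in a
#'   metacell (default `3`, i.e. 8-fold).
#' * `min_umis` -- minimum summed UMIs of the query and projected profile
#'   for a fold deviation to count (default `40`).
#' * `skew_min_fraction` -- a gene is type-skewed when strictly more than
#'   this fraction of the type's metacells are misfit for it (default `0.5`).
#' * `type_loop_max_rounds` -- maximum per-type filtering/re-projection
#'   rounds (default `3`).
#' * `max_misfit` -- a metacell with strictly more misfit fitted genes than
#'   this is unassigned (default `3`).
#' * `max_essential_fraction` -- a metacell whose fraction of misfit
#'   essential genes is at least this is unassigned (default `0.25`).
#' * `composite_enabled` -- whether unassigned metacells are tested as
#'   two-region composites (default `TRUE`).
#' * `n_closest_candidates`, `n_extra_candidates`, `max_candidate_distance` --
#'   the candidate-set rule: the `n_closest_candidates` atlas metacells
#'   nearest the anchor plus up to `n_extra_candidates` more within
#'   `max_candidate_distance` log2 units (defaults 10, 40, 2).
#' * `min_weight` -- mixture weights below this are removed and the rest
#'   renormalized (default `1e-5`).
#' * `solver_ridge` -- diagonal ridge stabilizing the quadratic program for
#'   collinear candidates (default `1e-10`).
#' * `verbose` -- emit per-stage progress messages (default `FALSE`).
#'
#' @return A named list of parameters.
#' @export
#' @examples
#' cfg <- proj_defaults()
#' cfg$epsilon
proj_defaults <- function() {
  list(
    epsilon = 1e-5,
    correct_genes = FALSE,
    correction_min_fit = 0.8,
    correction_min_factor = 1.15,
    correction_max_rounds = 3L,
    range_quantiles = c(0.02, 0.98),
    range_min_shared = 0.5,
    max_lfold = 3,
    min_umis = 40,
    skew_min_fraction = 0.5,
    type_loop_max_rounds = 3L,
    max_misfit = 3,
    max_essential_fraction = 0.25,
    composite_enabled = TRUE,
    n_closest_candidates = 10L,
    n_extra_candidates = 40L,
    max_candidate_distance = 2,
    min_weight = 1e-5,
    solver_ridge = 1e-10,
    verbose = FALSE
  )
}

## Merge user overrides into the defaults, rejecting unknown keys.
proj_config <- function(config = list(), ...) {
  defaults <- proj_defaults()
  overrides <- c(config, list(...))
  if (length(overrides) == 0L) {
    return(defaults)
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    abort(paste0("unknown configuration keys: ", paste(bad, collapse = ", ")))
  }
  modifyList(defaults, overrides)
}

amp_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) {
    inform(paste0(...))
  }
  invisible(NULL)
}
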