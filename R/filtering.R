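## Range-based gene filtering, fold deviations, type assignment and
## per-type skew filtering.

#' Filter genes by query/projection expression-range mismatch
#'
#' For every fitted, non-exempt gene, the query range is the 2%..98%
#' quantile interval of its (corrected) query log2 expression across
#' metacells, and similarly for the projected range. The gene is dropped
#' when the shared interval is strictly shorter than
#' `range_min_shared` (50%) of the query range. Genes with a zero query
#' range are kept. Quantiles use linear interpolation between order
#' statistics (R type 7), so results are bit-reproducible.
#'
#' @param e_query,e_projected Log2 expression matrices
#'   (metacells x genes).
#' @param fitted Logical vector over genes: the current fitted mask.
#' @param exempt Logical vector over genes exempt from this filter
#'   (noisy and lateral genes); exempt fitted genes are always kept.
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_range_filter` with the per-gene bounds
#'   (`low_query`, `high_query`, `low_projected`, `high_projected`,
#'   `low_shared`, `high_shared`), the `filtered` mask and the surviving
#'   `kept` mask (a subset of `fitted`).
#' @export
range_filter <- function(e_query, e_projected, fitted = NULL,
                         exempt = NULL, config = list()) {
  cfg <- proj_config(config)
  ng <- ncol(e_query)
  if (is.null(fitted)) fitted <- rep(TRUE, ng)
  if (is.null(exempt)) exempt <- rep(FALSE, ng)
  qs <- cfg$range_quantiles
  low_q <- apply(e_query, 2L, quantile, probs = qs[1], names = FALSE)
  high_q <- apply(e_query, 2L, quantile, probs = qs[2], names = FALSE)
  low_p <- apply(e_projected, 2L, quantile, probs = qs[1], names = FALSE)
  high_p <- apply(e_projected, 2L, quantile, probs = qs[2], names = FALSE)
  low_s <- pmax(low_q, low_p)
  high_s <- pmin(high_q, high_p)
  shared_len <- high_s - low_s # negative when the ranges are disjoint
  query_len <- high_q - low_q
  filtered <- fitted & !exempt & query_len > 0 &
    shared_len < cfg$range_min_shared * query_len
  structure(
    list(
      low_query = low_q, high_query = high_q,
      low_projected = low_p, high_projected = high_p,
      low_shared = low_s, high_shared = high_s,
      filtered = filtered,
      kept = fitted & !filtered
    ),
    class = "mc_range_filter"
  )
}

#' Per-gene, per-metacell fold deviations between query and projection
#'
#' `lfold = log2((epsilon + q) / (epsilon + p))` on linear fractions. The
#' misfit indicator `delta` requires both gates: `abs(lfold) > max_lfold`
#' (default 8-fold) *and* at least `min_umis` (default 40) UMIs summed over
#' the two profiles. Noisy and lateral genes never get `delta = TRUE`
#' (their mismatches are not negative evidence). Projected UMIs are the
#' projected fraction times the metacell's total, rounded.
#'
#' @param fr_query Corrected query fraction matrix (metacells x genes).
#' @param fr_projected Projected fraction matrix.
#' @param totals Per-metacell total UMI counts over the common genes.
#' @param exempt Logical vector over genes (noisy or lateral).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_deviation` with matrices `lfold`, `delta`,
#'   `umi_sum` and `umi_ok`.
#' @export
compute_deviation <- function(fr_query, fr_projected, totals,
                              exempt = NULL, config = list()) {
  cfg <- proj_config(config)
  if (is.null(exempt)) exempt <- rep(FALSE, ncol(fr_query))
  lfold <- log2((cfg$epsilon + fr_query) / (cfg$epsilon + fr_projected))
  umi_sum <- round(fr_query * totals) + round(fr_projected * totals)
  umi_ok <- umi_sum >= cfg$min_umis
  delta <- abs(lfold) > cfg$max_lfold & umi_ok
  delta[, exempt] <- FALSE
  structure(
    list(lfold = lfold, delta = delta, umi_sum = umi_sum, umi_ok = umi_ok),
    class = "mc_deviation"
  )
}

#' Assign a dominant atlas type to each query metacell
#'
#' The type whose atlas metacells carry the largest summed mixture weight.
#' Exact ties are broken toward the lexicographically first type label.
#'
#' @param weights Query-by-atlas weight matrix.
#' @param atlas_types Character vector of atlas metacell types (one per
#'   atlas metacell / column of `weights`).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return Character vector of assigned types, one per query metacell.
#' @export
assign_types <- function(weights, atlas_types, config = list()) {
  cfg <- proj_config(config)
  lv <- sort(unique(atlas_types))
  agg <- t(rowsum(t(weights), group = factor(atlas_types, levels = lv)))
  winners <- apply(agg, 1L, which.max) # first max = lexicographic tie-break
  ties <- apply(agg, 1L, function(x) sum(x == max(x)) > 1L)
  if (any(ties)) {
    amp_log(cfg, "type assignment: ", sum(ties),
            " metacell(s) tied; lexicographically first type used")
  }
  setNames(lv[winners], rownames(weights))
}

#' Per-type skewed-gene detection
#'
#' For every atlas type `t` and gene `g`, the skew is the fraction of
#' metacells assigned to `t` whose misfit indicator is set for `g`; genes
#' with skew strictly above `skew_min_fraction` (default 0.5) form the
#' type's skewed set.
#'
#' @param delta Logical misfit matrix (metacells x genes) from
#'   [compute_deviation()].
#' @param types Character vector of assigned types per query metacell.
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_type_skew` with the type-by-gene `skew`
#'   matrix and `skewed_genes`, a named list of per-type gene-index
#'   vectors.
#' @export
detect_type_skew <- function(delta, types, config = list()) {
  cfg <- proj_config(config)
  lv <- sort(unique(types))
  skew <- rowsum(delta + 0, group = factor(types, levels = lv)) /
    as.vector(table(factor(types, levels = lv)))
  skewed <- lapply(lv, function(t) {
    which(skew[t, ] > cfg$skew_min_fraction)
  })
  names(skewed) <- lv
  structure(
    list(skew = skew, skewed_genes = skewed),
    class = "mc_type_skew"
  )
}

## Iterate: re-project each metacell with its type's skewed genes removed
## from the fitted mask, then recompute types and skewed sets (accumulated
## across rounds). Stops when the type vector is unchanged, or after
## `type_loop_max_rounds` rounds.
type_filter_loop <- function(e_query, e_atlas, fr_query, totals,
                             kept_mask, exempt, atlas_types,
                             projection, types, cfg) {
  all_types <- sort(unique(atlas_types))
  skew_sets <- setNames(rep(list(integer()), length(all_types)), all_types)
  proj <- projection
  rounds <- 0L
  for (round in seq_len(cfg$type_loop_max_rounds)) {
    rounds <- round
    dev <- compute_deviation(fr_query, proj$fractions_projected, totals,
                             exempt = exempt, config = cfg)
    sk <- detect_type_skew(dev$delta, types, config = cfg)
    for (t in names(sk$skewed_genes)) {
      skew_sets[[t]] <- union(skew_sets[[t]], sk$skewed_genes[[t]])
    }
    masks_by_type <- lapply(setNames(all_types, all_types), function(t) {
      m <- kept_mask
      m[skew_sets[[t]]] <- FALSE
      m
    })
    proj_new <- project_all(
      e_query, e_atlas,
      gene_mask = masks_by_type[types],
      config = cfg
    )
    types_new <- assign_types(proj_new$weights, atlas_types, config = cfg)
    changed <- any(types_new != types)
    proj <- proj_new
    types <- types_new
    amp_log(cfg, "type-filter round ", round, ": ",
            sum(lengths(skew_sets)), " skewed gene-type pairs, ",
            if (changed) "types changed" else "types stable")
    if (!changed) break
  }
  masks_by_type <- lapply(setNames(all_types, all_types), function(t) {
    m <- kept_mask
    m[skew_sets[[t]]] <- FALSE
    m
  })
  list(
    projection = proj,
    types = types,
    skew_sets = skew_sets,
    masks_by_type = masks_by_type,
    rounds = rounds
  )
}
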