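## The full projection pipeline.

#' Project a query metacell dataset onto a reference atlas
#'
#' Runs the complete pipeline: common-gene initialization, seeding and
#' simplex-constrained mixture modelling, optional multiplicative gene
#' correction, range-based gene filtering, per-type skewed-gene filtering
#' with re-projection, composite (two-region) modelling of unassigned
#' metacells, and assembly of per-metacell / per-gene QC annotations.
#'
#' @param query An `mc_query` (see [query_model()], [load_query()]).
#' @param atlas An `mc_atlas` (see [atlas_model()], [load_atlas()]).
#' @param correct_genes Enable multiplicative technology-bias correction
#'   (overrides the config key of the same name).
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @param ... Individual parameter overrides, e.g. `epsilon = 1e-5`.
#' @return An object of class `mc_projection`; see [tidy.mc_projection()]
#'   and [glance.mc_projection()] for tabular views. Key components:
#'   `metacells` (per-metacell QC tibble), `gene_qc` (per-gene QC tibble),
#'   `weights` (query-by-atlas mixture weights), `projected_umis` and
#'   `corrected_umis` matrices.
#' @export
#' @examples
#' sc <- synth_scenario(n_types = 3, metacells_per_type = 4, n_genes = 300,
#'                      n_feature_genes = 80, umis_per_metacell = 8000)
#' atlas <- generate_atlas(sc)
#' res <- project_query(as_query(atlas), atlas)
#' glance(res)
project_query <- function(query, atlas, correct_genes = NULL,
                          config = list(), ...) {
  stopifnot(inherits(query, "mc_query"), inherits(atlas, "mc_atlas"))
  cfg <- proj_config(config, ...)
  if (!is.null(correct_genes)) {
    cfg$correct_genes <- isTRUE(correct_genes)
  }

  ## ---- initialization: common gene space -------------------------------
  gs <- intersect_genes(atlas, query)
  genes <- gs$genes
  uq <- query$umis[, gs$query_index, drop = FALSE]
  ua <- atlas$umis[, gs$atlas_index, drop = FALSE]
  colnames(uq) <- colnames(ua) <- genes
  feature <- genes %in% atlas$masks$feature
  exempt <- genes %in% atlas$masks$noisy | genes %in% atlas$masks$lateral
  essential_idx <- lapply(atlas$essential, function(g) {
    which(genes %in% g)
  })
  amp_log(cfg, "common gene space: ", length(genes), " genes (",
          sum(feature), " features)")

  xq <- compute_log_expression(uq, cfg$epsilon)
  xa <- compute_log_expression(ua, cfg$epsilon)
  atlas_types <- unname(atlas$types)

  ## ---- seeding, mixtures, and optional gene correction -----------------
  corr <- correction_loop(
    xq$e, xa$e, xq$fractions,
    gene_mask = feature, eligible = !exempt, cfg = cfg
  )
  e_q <- corr$e_query
  fr_q <- corr$fr_query
  types0 <- assign_types(corr$projection$weights, atlas_types, config = cfg)

  ## ---- range-based filtering ------------------------------------------
  rf <- range_filter(e_q, corr$projection$e_projected,
                     fitted = feature, exempt = exempt, config = cfg)
  kept <- rf$kept
  amp_log(cfg, "range filter: ", sum(rf$filtered), " gene(s) dropped, ",
          sum(kept), " fitted")
  proj1 <- project_all(e_q, xa$e, gene_mask = kept, config = cfg)
  types1 <- assign_types(proj1$weights, atlas_types, config = cfg)

  ## ---- per-type skewed-gene filtering ---------------------------------
  tl <- type_filter_loop(
    e_q, xa$e, fr_q, xq$totals, kept, exempt, atlas_types,
    projection = proj1, types = types1, cfg = cfg
  )
  proj <- tl$projection
  types <- tl$types
  masks_by_type <- tl$masks_by_type
  skew_sets <- tl$skew_sets

  ## ---- unassigned flags and composite projection ----------------------
  dev <- compute_deviation(fr_q, proj$fractions_projected, xq$totals,
                           exempt = exempt, config = cfg)
  flags <- flag_unassigned(dev, types, skew_sets, masks_by_type,
                           essential_idx, config = cfg)
  delta <- zero_type_skew(dev$delta, types, skew_sets)
  lfold <- dev$lfold
  umi_sum <- dev$umi_sum

  nq <- nrow(uq)
  composite_type <- rep("", nq)
  fitted_masks <- lapply(types, function(t) masks_by_type[[t]])
  W <- proj$weights
  e_p <- proj$e_projected
  fr_p <- proj$fractions_projected

  if (isTRUE(cfg$composite_enabled) && any(flags$unassigned)) {
    for (i in which(flags$unassigned)) {
      mask_i <- masks_by_type[[types[[i]]]]
      if (sum(mask_i) < 2L) next # nothing left to fit a second region on
      second <- residual_candidates(e_q[i, ], e_p[i, ], xa$e,
                                    gene_mask = mask_i, config = cfg)
      if (is.null(second)) next
      comp <- fit_composite(
        e_q[i, ], proj$candidates[[i]], second, xa$e,
        gene_mask = mask_i, fr_query_vec = fr_q[i, ],
        total = xq$totals[[i]], atlas_types = atlas_types,
        skew_sets = skew_sets, masks_by_type = masks_by_type,
        essential_idx = essential_idx, exempt = exempt, config = cfg
      )
      if (is.null(comp) || !comp$accepted) next
      amp_log(cfg, "metacell ", rownames(uq)[i], ": composite ",
              comp$primary_type, " + ", comp$secondary_type)
      types[[i]] <- comp$primary_type
      composite_type[[i]] <- comp$secondary_type
      fitted_masks[[i]] <- comp$fitted_mask
      W[i, ] <- 0
      W[i, as.integer(names(comp$weights))] <- comp$weights
      e_p[i, ] <- comp$e
      fr_p[i, ] <- comp$fractions
      # refresh the stored deviations for the composite projection
      dev_i <- compute_deviation(
        matrix(fr_q[i, ], 1L), matrix(comp$fractions, 1L), xq$totals[[i]],
        exempt = exempt, config = cfg
      )
      lfold[i, ] <- dev_i$lfold
      umi_sum[i, ] <- dev_i$umi_sum
      delta[i, ] <- comp$delta
      flags$misfit_count[[i]] <- comp$misfit_count
      flags$misfit_essential_fraction[[i]] <- comp$misfit_essential_fraction
      flags$unassigned[[i]] <- FALSE
    }
  }

  ## ---- QC assembly -----------------------------------------------------
  n_feature_common <- sum(feature)
  n_fitted <- unname(vapply(fitted_masks, sum, integer(1)))
  r2 <- compute_r2(e_q, e_p, fitted_masks)
  similar <- similar_mask(
    flags$misfit_count, flags$misfit_essential_fraction, n_fitted,
    n_feature_common, cfg
  )
  metacells <- tibble::tibble(
    metacell = rownames(uq),
    projected_type = unname(types),
    composite_type = composite_type,
    anchor = rownames(ua)[proj$anchors],
    n_fitted = n_fitted,
    misfit_count = as.numeric(flags$misfit_count),
    misfit_essential_fraction = flags$misfit_essential_fraction,
    similar = unname(similar),
    unassigned = flags$unassigned,
    r2 = r2,
    total_umis = unname(xq$totals)
  )
  gene_qc <- tibble::tibble(
    gene = genes,
    atlas_feature = feature,
    noisy = genes %in% atlas$masks$noisy,
    lateral = genes %in% atlas$masks$lateral,
    range_filtered = unname(rf$filtered),
    correlated = unname(corr$correlated),
    correction_factor = unname(corr$factor)
  )
  projected_umis <- round(fr_p * xq$totals)
  corrected_umis <- round(fr_q * xq$totals)
  structure(
    list(
      genes = genes,
      atlas_metacells = rownames(ua),
      atlas_types = atlas_types,
      query_metacells = rownames(uq),
      metacells = metacells,
      gene_qc = gene_qc,
      weights = W,
      e_query = e_q,
      e_projected = e_p,
      fractions_query = fr_q,
      fractions_projected = fr_p,
      totals = xq$totals,
      projected_umis = projected_umis,
      corrected_umis = corrected_umis,
      lfold = lfold,
      delta = delta,
      umi_sum = umi_sum,
      exempt = exempt,
      masks_by_type = masks_by_type,
      skew_sets = skew_sets,
      essential_idx = essential_idx,
      n_feature_common = n_feature_common,
      range_bounds = rf,
      correction_fit = corr$fit,
      config = cfg
    ),
    class = "mc_projection"
  )
}
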