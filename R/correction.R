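## Multiplicative technology-bias correction.

#' Estimate per-gene multiplicative corrections
#'
#' For every gene, computes `fit` -- the Pearson correlation between its
#' query and projected log2 expression across all query metacells -- and
#' the overall expression ratio `cf = sum_i p_gi / sum_i q_gi` on
#' linear-scale fractions. A gene is corrected when it is eligible (not
#' noisy or lateral), `fit > correction_min_fit`, and
#' `abs(log(cf)) > log(correction_min_factor)`; corrected genes get
#' `factor = cf` and all others `factor = 1`. The correction scales the
#' query fractions toward the projection (`corrected = factor * query`);
#' corrected fractions are deliberately not renormalized, so a correction
#' never leaks across genes.
#'
#' @param e_query,e_projected Log2 expression matrices (metacells x genes).
#' @param fr_query,fr_projected The matching linear-scale fractions.
#' @param eligible Logical vector over genes; ineligible genes (noisy,
#'   lateral) are never corrected. Default: all eligible.
#' @param config Named list of parameter overrides (see [proj_defaults()]).
#' @return A list of class `mc_correction` with per-gene `fit`, `factor`,
#'   `correlated` (genes passing the fit gate) and `corrected` masks.
#' @export
estimate_corrections <- function(e_query, e_projected, fr_query,
                                 fr_projected, eligible = NULL,
                                 config = list()) {
  cfg <- proj_config(config)
  ng <- ncol(e_query)
  if (is.null(eligible)) {
    eligible <- rep(TRUE, ng)
  }
  # per-gene correlation over metacells; zero variance -> 0
  fit <- suppressWarnings(
    vapply(seq_len(ng), function(g) {
      stats::cor(e_query[, g], e_projected[, g])
    }, numeric(1))
  )
  fit[!is.finite(fit)] <- 0
  q_tot <- colSums(fr_query)
  p_tot <- colSums(fr_projected)
  cf <- ifelse(q_tot > 0, p_tot / q_tot, 1)
  zero_q <- q_tot == 0 & p_tot > 0
  if (any(zero_q)) {
    amp_log(cfg, "correction: ", sum(zero_q),
            " gene(s) with zero query expression kept uncorrected")
  }
  correlated <- eligible & fit > cfg$correction_min_fit
  corrected <- correlated & cf > 0 &
    abs(log(cf)) > log(cfg$correction_min_factor)
  factor <- ifelse(corrected, cf, 1)
  structure(
    list(
      fit = fit,
      factor = factor,
      correlated = correlated,
      corrected = corrected
    ),
    class = "mc_correction"
  )
}

## Alternates correction estimation and re-projection until a round
## corrects no genes, or `correction_max_rounds` rounds elapse. Returns the
## final projection together with the corrected query expression and the
## per-gene accumulated factor (product over rounds).
correction_loop <- function(e_query, e_atlas, fr_query, gene_mask,
                            eligible, cfg) {
  accum <- rep(1, ncol(e_query))
  fit_last <- rep(0, ncol(e_query))
  correlated <- rep(FALSE, ncol(e_query))
  fr_work <- fr_query
  e_work <- e_query
  proj <- project_all(e_work, e_atlas, gene_mask, cfg)
  if (isTRUE(cfg$correct_genes)) {
    for (round in seq_len(cfg$correction_max_rounds)) {
      est <- estimate_corrections(
        e_work, proj$e_projected, fr_work, proj$fractions_projected,
        eligible = eligible, config = cfg
      )
      fit_last <- est$fit
      correlated <- correlated | est$correlated
      if (!any(est$corrected)) {
        amp_log(cfg, "correction round ", round, ": no genes corrected")
        break
      }
      amp_log(cfg, "correction round ", round, ": ",
              sum(est$corrected), " gene(s) corrected")
      accum <- accum * est$factor
      fr_work <- sweep(fr_work, 2L, est$factor, "*")
      e_work <- log2(cfg$epsilon + fr_work)
      proj <- project_all(e_work, e_atlas, gene_mask, cfg)
    }
  }
  list(
    projection = proj,
    e_query = e_work,
    fr_query = fr_work,
    factor = accum,
    fit = fit_last,
    correlated = correlated
  )
}
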