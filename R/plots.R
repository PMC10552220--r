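## Diagnostic plots.

#' Diagnostic plots for a projection result
#'
#' @param object An `mc_projection` from [project_query()].
#' @param type One of `"r2"` (distribution of per-metacell observed vs
#'   projected r2), `"correction"` (per-gene query/projection correlation
#'   against the inferred correction factor, corrected genes highlighted),
#'   or `"expression"` (observed vs projected log2 expression for one
#'   metacell).
#' @param metacell Query metacell name for `type = "expression"`
#'   (default: the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_projection
#' @export
autoplot.mc_projection <- function(object, type = c("r2", "correction",
                                                    "expression"),
                                   metacell = NULL, ...) {
  type <- match.arg(type)
  if (type == "r2") {
    df <- object$metacells
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$r2)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey30") +
        ggplot2::labs(
          x = expression(r^2 ~ "(observed vs projected, fitted genes)"),
          y = "metacells"
        ) +
        ggplot2::theme_minimal()
    )
  }
  if (type == "correction") {
    df <- tibble::tibble(
      fit = object$correction_fit,
      factor = object$gene_qc$correction_factor,
      corrected = object$gene_qc$correction_factor != 1
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$fit,
                                       y = log2(.data$factor),
                                       colour = .data$corrected)) +
        ggplot2::geom_point(size = 0.8, alpha = 0.7) +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                                `TRUE` = "red3")) +
        ggplot2::labs(x = "query/projection correlation (fit)",
                      y = "log2 correction factor") +
        ggplot2::theme_minimal()
    )
  }
  i <- if (is.null(metacell)) 1L else match(metacell, object$query_metacells)
  if (is.na(i)) {
    abort(paste0("unknown query metacell: ", metacell))
  }
  t_i <- object$metacells$projected_type[[i]]
  df <- tibble::tibble(
    observed = object$e_query[i, ],
    projected = object$e_projected[i, ],
    fitted = object$masks_by_type[[t_i]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$projected, y = .data$observed,
                                   colour = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "steelblue4")) +
    ggplot2::labs(
      title = paste0(object$query_metacells[[i]], " (", t_i, ")"),
      x = "projected log2 expression", y = "observed log2 expression"
    ) +
    ggplot2::theme_minimal()
}
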