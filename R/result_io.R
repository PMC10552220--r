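## Writing and re-loading projection results.

write_real_mtx <- function(m, path) {
  sm <- Matrix::Matrix(m, sparse = TRUE)
  sm <- methods::as(sm, "generalMatrix")
  Matrix::writeMM(sm, path)
  invisible(path)
}

mask_list_to_tsv <- function(sets, genes, path, value_name = "gene") {
  df <- tibble::tibble(
    type = rep(names(sets), vapply(sets, length, integer(1))),
    gene = genes[unlist(sets, use.names = FALSE) %||% integer()]
  )
  names(df)[2] <- value_name
  readr::write_tsv(df, path)
}

#' Write a projection result to a directory
#'
#' Emits flat TSV summaries (`metacell_qc.tsv`, `gene_qc.tsv`,
#' `type_skewed_genes.tsv`, `fitted_genes.tsv`, `essential_genes.tsv`,
#' `atlas_metacells.tsv`, `config.tsv`) together with MatrixMarket layers:
#' the mixture weights (`atlas_weights.mtx`), the projected and corrected
#' UMIs (`projected_umis.mtx`, `corrected_umis.mtx`), and the per-gene
#' fold deviations (`lfold.mtx`, `umi_sum.mtx`) that allow the misfit QC
#' to be recomputed at a different threshold later.
#'
#' @param result An `mc_projection` from [project_query()].
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "mc_projection"))
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(paste0("cannot create result directory: ", path))
  }
  readr::write_tsv(result$metacells, file.path(path, "metacell_qc.tsv"))
  readr::write_tsv(result$gene_qc, file.path(path, "gene_qc.tsv"))
  mask_list_to_tsv(result$skew_sets, result$genes,
                   file.path(path, "type_skewed_genes.tsv"))
  fitted_sets <- lapply(result$masks_by_type, which)
  mask_list_to_tsv(fitted_sets, result$genes,
                   file.path(path, "fitted_genes.tsv"))
  mask_list_to_tsv(result$essential_idx, result$genes,
                   file.path(path, "essential_genes.tsv"))
  readr::write_tsv(
    tibble::tibble(metacell = result$atlas_metacells,
                   type = result$atlas_types),
    file.path(path, "atlas_metacells.tsv")
  )
  write_real_mtx(result$weights, file.path(path, "atlas_weights.mtx"))
  write_real_mtx(result$projected_umis, file.path(path, "projected_umis.mtx"))
  write_real_mtx(result$corrected_umis, file.path(path, "corrected_umis.mtx"))
  write_real_mtx(result$lfold, file.path(path, "lfold.mtx"))
  write_real_mtx(result$umi_sum, file.path(path, "umi_sum.mtx"))
  readr::write_tsv(
    tibble::tibble(gene = result$genes, exempt = result$exempt),
    file.path(path, "exempt_genes.tsv")
  )
  scalars <- result$config[vapply(result$config, function(x) {
    length(x) == 1L && (is.numeric(x) || is.logical(x))
  }, logical(1))]
  readr::write_tsv(
    tibble::tibble(
      key = names(scalars),
      value = vapply(scalars, function(x) format(x, digits = 17), character(1))
    ),
    file.path(path, "config.tsv")
  )
  invisible(path)
}

read_named_mtx <- function(path, rows, cols) {
  m <- as.matrix(Matrix::readMM(path))
  dimnames(m) <- list(rows, cols)
  m
}

#' Reload a projection result directory
#'
#' Reconstructs an `mc_projection` carrying everything needed for QC
#' re-thresholding ([recompute_misfits()]) and the tabular accessors; the
#' expression matrices themselves are not persisted.
#'
#' @param path Directory written by [write_result()].
#' @return An `mc_projection`.
#' @export
read_result <- function(path) {
  if (!dir.exists(path)) {
    abort(paste0("result directory not found: ", path))
  }
  metacells <- read_tsv_quiet(file.path(path, "metacell_qc.tsv"))
  metacells$composite_type <-
    ifelse(is.na(metacells$composite_type), "", metacells$composite_type)
  gene_qc <- read_tsv_quiet(file.path(path, "gene_qc.tsv"))
  genes <- gene_qc$gene
  am <- read_tsv_quiet(file.path(path, "atlas_metacells.tsv"))
  skew <- read_tsv_quiet(file.path(path, "type_skewed_genes.tsv"))
  fitted <- read_tsv_quiet(file.path(path, "fitted_genes.tsv"))
  ess <- read_tsv_quiet(file.path(path, "essential_genes.tsv"))
  exempt_df <- read_tsv_quiet(file.path(path, "exempt_genes.tsv"))
  cfg_df <- read_tsv_quiet(file.path(path, "config.tsv"))
  cfg <- proj_defaults()
  for (i in seq_len(nrow(cfg_df))) {
    key <- cfg_df$key[[i]]
    old <- cfg[[key]]
    cfg[[key]] <- if (is.logical(old)) {
      as.logical(cfg_df$value[[i]])
    } else if (is.integer(old)) {
      as.integer(cfg_df$value[[i]])
    } else {
      as.numeric(cfg_df$value[[i]])
    }
  }
  types_present <- sort(unique(am$type))
  sets_from_tsv <- function(df, col = "gene") {
    out <- setNames(rep(list(integer()), length(types_present)),
                    types_present)
    if (nrow(df) > 0L) {
      for (t in unique(df$type)) {
        out[[t]] <- match(df[[col]][df$type == t], genes)
      }
    }
    out
  }
  skew_sets <- sets_from_tsv(skew)
  essential_idx <- sets_from_tsv(ess)
  fitted_sets <- sets_from_tsv(fitted)
  masks_by_type <- lapply(fitted_sets, function(idx) {
    m <- rep(FALSE, length(genes))
    m[idx] <- TRUE
    m
  })
  structure(
    list(
      genes = genes,
      atlas_metacells = am$metacell,
      atlas_types = am$type,
      query_metacells = metacells$metacell,
      metacells = metacells,
      gene_qc = gene_qc,
      weights = read_named_mtx(file.path(path, "atlas_weights.mtx"),
                               metacells$metacell, am$metacell),
      projected_umis = read_named_mtx(file.path(path, "projected_umis.mtx"),
                                      metacells$metacell, genes),
      corrected_umis = read_named_mtx(file.path(path, "corrected_umis.mtx"),
                                      metacells$metacell, genes),
      lfold = read_named_mtx(file.path(path, "lfold.mtx"),
                             metacells$metacell, genes),
      umi_sum = read_named_mtx(file.path(path, "umi_sum.mtx"),
                               metacells$metacell, genes),
      delta = NULL,
      totals = setNames(metacells$total_umis, metacells$metacell),
      exempt = exempt_df$exempt,
      masks_by_type = masks_by_type,
      skew_sets = skew_sets,
      essential_idx = essential_idx,
      n_feature_common = sum(gene_qc$atlas_feature),
      config = cfg
    ),
    class = "mc_projection"
  )
}
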