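## On-disk bundles: MatrixMarket counts plus TSV sidecars.
##
## A bundle is a directory with:
##   matrix.mtx      metacell x gene counts (MatrixMarket)
##   genes.tsv       column `gene`, in matrix column order
##   metacells.tsv   column `metacell` (+ `type` for atlases, optional `cells`)
##   masks.tsv       atlas only: gene, feature_gene, noisy_gene, lateral_gene
##   essential.tsv   atlas only: type, gene
## Counts are written and re-read as exact integers.

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

require_file <- function(dir, name, what) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    abort(paste0(what, ": missing '", name, "' in bundle ", dir))
  }
  path
}

read_bundle_counts <- function(path, what) {
  if (!dir.exists(path)) {
    abort(paste0(what, ": bundle directory not found: ", path))
  }
  mtx <- require_file(path, "matrix.mtx", what)
  genes <- read_tsv_quiet(require_file(path, "genes.tsv", what))
  if (!"gene" %in% names(genes)) {
    abort(paste0(what, ": genes.tsv must have a 'gene' column"))
  }
  mcs <- read_tsv_quiet(require_file(path, "metacells.tsv", what))
  if (!"metacell" %in% names(mcs)) {
    abort(paste0(what, ": metacells.tsv must have a 'metacell' column"))
  }
  counts <- as.matrix(Matrix::readMM(mtx))
  if (nrow(counts) != nrow(mcs) || ncol(counts) != nrow(genes)) {
    abort(paste0(
      what, ": matrix.mtx is ", nrow(counts), " x ", ncol(counts),
      " but the sidecars describe ", nrow(mcs), " metacells x ",
      nrow(genes), " genes; metacells must be rows and genes columns"
    ))
  }
  dimnames(counts) <- list(mcs$metacell, genes$gene)
  list(counts = counts, metacells = mcs, genes = genes)
}

#' Load a reference atlas from a bundle directory
#'
#' Reads the MatrixMarket + TSV bundle written by [write_atlas()] and
#' validates it through [atlas_model()]. `metacells.tsv` must carry the
#' `type` column; gene masks come from `masks.tsv` and per-type essential
#' genes from `essential.tsv`.
#'
#' @param path Bundle directory.
#' @inheritParams atlas_model
#' @return A validated `mc_atlas`.
#' @export
load_atlas <- function(path, exclude_genes = NULL, case_fold = FALSE) {
  raw <- read_bundle_counts(path, "atlas")
  if (!"type" %in% names(raw$metacells)) {
    abort("atlas: metacells.tsv is missing the 'types' annotation column 'type'")
  }
  masks <- read_tsv_quiet(require_file(path, "masks.tsv", "atlas"))
  needed <- c("gene", "feature_gene", "noisy_gene", "lateral_gene")
  if (!all(needed %in% names(masks))) {
    abort(paste0(
      "atlas: masks.tsv must have columns ",
      paste(needed, collapse = ", ")
    ))
  }
  ess_path <- file.path(path, "essential.tsv")
  essential <- list()
  if (file.exists(ess_path)) {
    ess <- read_tsv_quiet(ess_path)
    if (!all(c("type", "gene") %in% names(ess))) {
      abort("atlas: essential.tsv must have columns type, gene")
    }
    if (nrow(ess) > 0L) {
      essential <- split(ess$gene, ess$type)
    }
  }
  cells <- if ("cells" %in% names(raw$metacells)) raw$metacells$cells
  atlas_model(
    raw$counts,
    types = raw$metacells$type,
    feature_genes = masks$gene[as.logical(masks$feature_gene)],
    noisy_genes = masks$gene[as.logical(masks$noisy_gene)],
    lateral_genes = masks$gene[as.logical(masks$lateral_gene)],
    essential_genes = essential,
    cell_counts = cells,
    exclude_genes = exclude_genes,
    case_fold = case_fold
  )
}

#' Load a query from a bundle directory
#'
#' @param path Bundle directory (as written by [write_query()]).
#' @inheritParams query_model
#' @return A validated `mc_query`.
#' @export
load_query <- function(path, case_fold = FALSE) {
  raw <- read_bundle_counts(path, "query")
  cells <- if ("cells" %in% names(raw$metacells)) raw$metacells$cells
  query_model(raw$counts, cell_counts = cells, case_fold = case_fold)
}

write_counts_mtx <- function(counts, path) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(m, "generalMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' Write an atlas to a bundle directory
#'
#' @param atlas An `mc_atlas`.
#' @param path Directory to create (or overwrite files in).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "mc_atlas"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(atlas$umis, file.path(path, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(gene = atlas$gene_names),
    file.path(path, "genes.tsv")
  )
  mcs <- tibble::tibble(
    metacell = rownames(atlas$umis),
    type = unname(atlas$types)
  )
  if (!is.null(atlas$cell_counts)) {
    mcs$cells <- atlas$cell_counts
  }
  readr::write_tsv(mcs, file.path(path, "metacells.tsv"))
  readr::write_tsv(
    tibble::tibble(
      gene = atlas$gene_names,
      feature_gene = atlas$gene_names %in% atlas$masks$feature,
      noisy_gene = atlas$gene_names %in% atlas$masks$noisy,
      lateral_gene = atlas$gene_names %in% atlas$masks$lateral
    ),
    file.path(path, "masks.tsv")
  )
  ess <- tibble::tibble(
    type = rep(names(atlas$essential), lengths(atlas$essential)),
    gene = unlist(atlas$essential, use.names = FALSE) %||% character()
  )
  readr::write_tsv(ess, file.path(path, "essential.tsv"))
  invisible(path)
}

#' Write a query to a bundle directory
#'
#' @param query An `mc_query`.
#' @param path Directory to create (or overwrite files in).
#' @return `path`, invisibly.
#' @export
write_query <- function(query, path) {
  stopifnot(inherits(query, "mc_query"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(query$umis, file.path(path, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(gene = query$gene_names),
    file.path(path, "genes.tsv")
  )
  mcs <- tibble::tibble(metacell = rownames(query$umis))
  if (!is.null(query$cell_counts)) {
    mcs$cells <- query$cell_counts
  }
  readr::write_tsv(mcs, file.path(path, "metacells.tsv"))
  invisible(path)
}
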