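## Atlas and query containers, validation, and the common gene space.

as_count_matrix <- function(umis, what) {
  if (inherits(umis, "Matrix")) {
    umis <- as.matrix(umis)
  }
  if (!is.matrix(umis) || !is.numeric(umis)) {
    abort(paste0(what, ": umis must be a numeric metacell x gene matrix"))
  }
  if (anyNA(umis)) {
    abort(paste0(what, ": umis contains missing values"))
  }
  if (any(umis < 0)) {
    abort(paste0(what, ": umis contains negative counts"))
  }
  if (any(abs(umis - round(umis)) > 1e-8)) {
    abort(paste0(what, ": umis contains non-integer counts"))
  }
  storage.mode(umis) <- "double"
  if (is.null(colnames(umis))) {
    abort(paste0(what, ": umis must have gene names as column names"))
  }
  if (anyDuplicated(colnames(umis))) {
    dup <- unique(colnames(umis)[duplicated(colnames(umis))])
    abort(paste0(
      what, ": duplicate gene names (ambiguous mapping): ",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  if (is.null(rownames(umis))) {
    rownames(umis) <- sprintf("mc%03d", seq_len(nrow(umis)))
  }
  if (anyDuplicated(rownames(umis))) {
    abort(paste0(what, ": duplicate metacell names"))
  }
  zero <- rowSums(umis) == 0
  if (any(zero)) {
    abort(paste0(
      what, ": metacells with zero total UMIs: ",
      paste(head(rownames(umis)[zero], 5L), collapse = ", ")
    ))
  }
  umis
}

check_genes_in_universe <- function(genes, universe, what) {
  missing <- setdiff(genes, universe)
  if (length(missing) > 0L) {
    abort(paste0(
      what, " not in the gene universe: ",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  invisible(NULL)
}

#' Construct and validate a reference atlas
#'
#' An atlas bundles a metacell-by-gene UMI count matrix with the gene masks
#' (feature / noisy / lateral), one type annotation per metacell, and an
#' optional small set of essential marker genes per type. Excluded genes
#' (e.g. mitochondrial) are assumed to have been removed before atlas
#' construction; an optional `exclude_genes` list drops columns up front for
#' users starting from raw matrices.
#'
#' @param umis Numeric matrix of non-negative integer UMI counts, metacells
#'   as rows, genes as columns (column names are the gene universe).
#' @param types Character vector, one type label per metacell.
#' @param feature_genes Character vector of genes allowed to drive the fit.
#' @param noisy_genes,lateral_genes Character vectors of genes whose
#'   mismatches are never used as negative evidence. Lateral genes may not
#'   also be feature genes.
#' @param essential_genes Named list mapping a type label to a character
#'   vector of essential marker genes for that type.
#' @param cell_counts Optional per-metacell cell counts (reporting only).
#' @param exclude_genes Optional genes to drop before any computation.
#' @param case_fold If `TRUE`, gene identifiers are lower-cased before
#'   matching (no alias translation is ever attempted).
#' @return An object of class `mc_atlas`.
#' @export
#' @examples
#' u <- matrix(c(5, 0, 3, 1, 2, 4), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("a", "b", "c")))
#' atlas_model(u, types = c("T", "T"), feature_genes = c("a", "b"))
atlas_model <- function(umis, types, feature_genes,
                        noisy_genes = character(),
                        lateral_genes = character(),
                        essential_genes = list(),
                        cell_counts = NULL,
                        exclude_genes = NULL,
                        case_fold = FALSE) {
  umis <- as_count_matrix(umis, "atlas")
  if (isTRUE(case_fold)) {
    colnames(umis) <- tolower(colnames(umis))
    feature_genes <- tolower(feature_genes)
    noisy_genes <- tolower(noisy_genes)
    lateral_genes <- tolower(lateral_genes)
    essential_genes <- lapply(essential_genes, tolower)
    exclude_genes <- if (!is.null(exclude_genes)) tolower(exclude_genes)
  }
  if (!is.null(exclude_genes)) {
    keep <- !(colnames(umis) %in% exclude_genes)
    umis <- umis[, keep, drop = FALSE]
    feature_genes <- setdiff(feature_genes, exclude_genes)
    noisy_genes <- setdiff(noisy_genes, exclude_genes)
    lateral_genes <- setdiff(lateral_genes, exclude_genes)
    essential_genes <- lapply(essential_genes, setdiff, y = exclude_genes)
    zero <- rowSums(umis) == 0
    if (any(zero)) {
      abort(paste0(
        "atlas: metacells with zero total UMIs after exclusion: ",
        paste(head(rownames(umis)[zero], 5L), collapse = ", ")
      ))
    }
  }
  universe <- colnames(umis)
  if (is.null(types) || length(types) != nrow(umis)) {
    abort("atlas: `types` must hold exactly one label per metacell")
  }
  types <- as.character(types)
  if (anyNA(types) || any(types == "")) {
    abort("atlas: `types` contains missing or empty labels")
  }
  check_genes_in_universe(feature_genes, universe, "atlas: feature genes")
  check_genes_in_universe(noisy_genes, universe, "atlas: noisy genes")
  check_genes_in_universe(lateral_genes, universe, "atlas: lateral genes")
  clash <- intersect(feature_genes, lateral_genes)
  if (length(clash) > 0L) {
    abort(paste0(
      "atlas: lateral genes may not be feature genes: ",
      paste(head(clash, 5L), collapse = ", ")
    ))
  }
  if (length(essential_genes) > 0L && is.null(names(essential_genes))) {
    abort("atlas: `essential_genes` must be a named list (type -> genes)")
  }
  for (t in names(essential_genes)) {
    check_genes_in_universe(
      essential_genes[[t]], universe,
      paste0("atlas: essential genes of type '", t, "'")
    )
  }
  if (!is.null(cell_counts) && length(cell_counts) != nrow(umis)) {
    abort("atlas: `cell_counts` must have one entry per metacell")
  }
  structure(
    list(
      umis = umis,
      gene_names = universe,
      masks = list(
        feature = unique(feature_genes),
        noisy = unique(noisy_genes),
        lateral = unique(lateral_genes)
      ),
      types = setNames(types, rownames(umis)),
      essential = lapply(essential_genes, unique),
      cell_counts = cell_counts
    ),
    class = "mc_atlas"
  )
}

#' Construct and validate a query metacell model
#'
#' @param umis Numeric matrix of non-negative integer UMI counts, metacells
#'   as rows, genes as columns.
#' @param cell_counts Optional per-metacell cell counts (reporting only).
#' @param case_fold If `TRUE`, gene identifiers are lower-cased.
#' @return An object of class `mc_query`.
#' @export
query_model <- function(umis, cell_counts = NULL, case_fold = FALSE) {
  umis <- as_count_matrix(umis, "query")
  if (isTRUE(case_fold)) {
    colnames(umis) <- tolower(colnames(umis))
  }
  if (!is.null(cell_counts) && length(cell_counts) != nrow(umis)) {
    abort("query: `cell_counts` must have one entry per metacell")
  }
  structure(
    list(
      umis = umis,
      gene_names = colnames(umis),
      cell_counts = cell_counts
    ),
    class = "mc_query"
  )
}

#' Treat an atlas as a query
#'
#' Convenience for self-projection experiments: reuses the atlas count
#' matrix as a query model.
#'
#' @param atlas An `mc_atlas`.
#' @return An `mc_query` over the same metacells and genes.
#' @export
as_query <- function(atlas) {
  stopifnot(inherits(atlas, "mc_atlas"))
  query_model(atlas$umis, cell_counts = atlas$cell_counts)
}

#' Common gene space of an atlas and a query
#'
#' Genes are matched by exact identifier equality; the intersection is kept
#' in atlas gene order. Only genes in the intersection take part in any
#' downstream computation.
#'
#' @param atlas An `mc_atlas`.
#' @param query An `mc_query`.
#' @return A list of class `mc_gene_space` with elements `genes` (ordered
#'   identifiers), `atlas_index` and `query_index` (column indices into the
#'   respective matrices).
#' @export
#' @examples
#' a <- atlas_model(
#'   matrix(1:6, 2, dimnames = list(NULL, c("A", "B", "C"))),
#'   types = c("x", "x"), feature_genes = c("A", "B")
#' )
#' q <- query_model(matrix(1:6, 2, dimnames = list(NULL, c("B", "C", "D"))))
#' intersect_genes(a, q)$genes
intersect_genes <- function(atlas, query) {
  stopifnot(inherits(atlas, "mc_atlas"), inherits(query, "mc_query"))
  genes <- atlas$gene_names[atlas$gene_names %in% query$gene_names]
  if (length(genes) == 0L) {
    abort("empty common gene space: the atlas and query share no genes")
  }
  n_feature <- sum(atlas$masks$feature %in% genes)
  if (n_feature < 2L) {
    abort(paste0(
      "common gene space contains only ", n_feature,
      " atlas feature gene(s); projection is impossible"
    ))
  }
  structure(
    list(
      genes = genes,
      atlas_index = match(genes, atlas$gene_names),
      query_index = match(genes, query$gene_names)
    ),
    class = "mc_gene_space"
  )
}

#' @export
print.mc_atlas <- function(x, ...) {
  cat(
    "metacell atlas: ", nrow(x$umis), " metacells x ", ncol(x$umis),
    " genes, ", length(unique(x$types)), " types\n",
    "  feature genes: ", length(x$masks$feature),
    ", noisy: ", length(x$masks$noisy),
    ", lateral: ", length(x$masks$lateral),
    ", essential sets: ", length(x$essential), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.mc_query <- function(x, ...) {
  cat(
    "query metacells: ", nrow(x$umis), " metacells x ", ncol(x$umis),
    " genes\n",
    sep = ""
  )
  invisible(x)
}
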