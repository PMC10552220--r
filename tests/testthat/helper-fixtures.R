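# Small deterministic fixtures shared across the test files.

named_counts <- function(values, nrow, genes, metacells = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  colnames(m) <- genes
  rownames(m) <- metacells %||% sprintf("mc%02d", seq_len(nrow))
  m
}

# a minimal valid atlas: 3 metacells, 5 genes, 1 type
tiny_atlas <- function() {
  u <- named_counts(
    c(
      10, 5, 0, 3, 2,
      8, 6, 1, 2, 3,
      1, 2, 9, 8, 0
    ),
    nrow = 3, genes = paste0("g", 1:5)
  )
  atlas_model(
    u,
    types = c("A", "A", "B"),
    feature_genes = c("g1", "g2", "g3", "g4"),
    essential_genes = list(A = "g1", B = "g3")
  )
}

# a small but realistic seeded scenario for pipeline-level unit tests;
# any synth_scenario() argument can be overridden
small_scenario <- function(...) {
  args <- utils::modifyList(
    list(
      n_types = 4, metacells_per_type = 6, n_genes = 600,
      n_feature_genes = 150, umis_per_metacell = 20000,
      n_markers = 20, n_essential = 3, seed = 11
    ),
    list(...)
  )
  do.call(synth_scenario, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
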