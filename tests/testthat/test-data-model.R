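# Containers, validation, gene intersection, and bundle IO.

test_that("atlas and query constructors validate their invariants", {
  u <- named_counts(c(1, 2, 3, 4), 2, c("g1", "g2"))
  expect_s3_class(atlas_model(u, c("A", "B"), feature_genes = c("g1", "g2")),
                  "mc_atlas")

  expect_error(atlas_model(u, NULL, feature_genes = "g1"), "types")
  expect_error(atlas_model(u, "A", feature_genes = "g1"), "one label")
  expect_error(
    atlas_model(u, c("A", "B"), feature_genes = "nope"),
    "feature genes"
  )
  expect_error(
    atlas_model(u, c("A", "B"), feature_genes = "g1",
                essential_genes = list(A = "nope")),
    "essential"
  )
  expect_error(
    atlas_model(u, c("A", "B"), feature_genes = "g1", lateral_genes = "g1"),
    "lateral"
  )

  neg <- u; neg[1, 1] <- -1
  expect_error(query_model(neg), "negative")
  zero <- u; zero[1, ] <- 0
  expect_error(query_model(zero), "zero total UMIs")
  dup <- u; colnames(dup) <- c("g1", "g1")
  expect_error(query_model(dup), "duplicate gene names")
})

test_that("excluded genes are dropped before any computation", {
  u <- named_counts(c(1, 2, 3, 4, 5, 6), 2, c("g1", "g2", "mt1"))
  a <- atlas_model(u, c("A", "A"), feature_genes = c("g1", "g2"),
                   exclude_genes = "mt1")
  expect_identical(a$gene_names, c("g1", "g2"))
  expect_identical(dim(a$umis), c(2L, 2L))
})

test_that("gene intersection keeps atlas order and checks feasibility", {
  a <- atlas_model(named_counts(1:6, 2, c("A", "B", "C")), c("x", "x"),
                   feature_genes = c("B", "C"))
  q <- query_model(named_counts(1:6, 2, c("B", "C", "D")))
  gs <- intersect_genes(a, q)
  expect_identical(gs$genes, c("B", "C"))
  expect_identical(gs$atlas_index, c(2L, 3L))
  expect_identical(gs$query_index, c(1L, 2L))
  # membership symmetry
  expect_setequal(gs$genes, intersect(a$gene_names, q$gene_names))

  # identical gene lists: identity indices
  q2 <- query_model(named_counts(1:6, 2, c("A", "B", "C")))
  gs2 <- intersect_genes(a, q2)
  expect_identical(gs2$genes, a$gene_names)
  expect_identical(gs2$atlas_index, 1:3)

  # disjoint: impossible
  q3 <- query_model(named_counts(1:4, 2, c("X", "Y")))
  expect_error(intersect_genes(a, q3), "empty common gene space")
  # a single shared feature gene is not enough either
  q4 <- query_model(named_counts(1:4, 2, c("A", "B")))
  expect_error(intersect_genes(a, q4), "feature gene")
})

test_that("atlas bundles round-trip bit-exactly", {
  atlas <- tiny_atlas()
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  back <- load_atlas(dir)
  expect_identical(back$umis, atlas$umis)
  expect_identical(back$types, atlas$types)
  expect_identical(back$masks, atlas$masks)
  expect_identical(back$essential[order(names(back$essential))],
                   atlas$essential[order(names(atlas$essential))])

  # re-saving the loaded atlas reproduces identical matrices
  dir2 <- withr::local_tempdir()
  write_atlas(back, dir2)
  expect_identical(load_atlas(dir2)$umis, atlas$umis)
})

test_that("generated fixtures round-trip through the loaders", {
  sc <- synth_scenario(n_types = 2, metacells_per_type = 3, n_genes = 60,
                       n_feature_genes = 20, umis_per_metacell = 2000,
                       n_markers = 5, n_essential = 2, seed = 7)
  atlas <- generate_atlas(sc)
  q <- generate_query(synth_scenario(
    n_types = 2, metacells_per_type = 3, n_genes = 60,
    n_feature_genes = 20, umis_per_metacell = 2000, n_markers = 5,
    n_essential = 2, n_mixture_queries = 4, seed = 7
  ))
  dir <- withr::local_tempdir()
  write_atlas(atlas, file.path(dir, "a"))
  write_query(q$query, file.path(dir, "q"))
  expect_identical(load_atlas(file.path(dir, "a"))$umis, atlas$umis)
  expect_identical(load_query(file.path(dir, "q"))$umis, q$query$umis)
})

test_that("a bundle without the type column names the missing field", {
  atlas <- tiny_atlas()
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  mcs <- readr::read_tsv(file.path(dir, "metacells.tsv"),
                         show_col_types = FALSE)
  readr::write_tsv(mcs["metacell"], file.path(dir, "metacells.tsv"))
  expect_error(load_atlas(dir), "types")
})
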