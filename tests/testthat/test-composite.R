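# Unassigned flags and two-region composite fits.

# a deviation object with a prescribed delta matrix
delta_fixture <- function(delta) {
  structure(
    list(
      lfold = delta * 4, # consistent with |lfold| > 3 where delta is set
      delta = delta,
      umi_sum = matrix(100, nrow(delta), ncol(delta)),
      umi_ok = matrix(TRUE, nrow(delta), ncol(delta))
    ),
    class = "mc_deviation"
  )
}

test_that("unassignment follows the misfit and essential-gene boundaries", {
  ng <- 10
  fitted <- rep(TRUE, ng)
  # metacell 1: 4 misfit genes (> 3): unassigned
  # metacell 2: 3 misfit genes, no essentials hit: assigned (boundary)
  # metacell 3: clean fit but 1 of 4 essentials misfit (0.25): unassigned
  delta <- rbind(
    c(rep(TRUE, 4), rep(FALSE, 6)),
    c(rep(TRUE, 3), rep(FALSE, 7)),
    c(rep(FALSE, 6), TRUE, rep(FALSE, 3))
  )
  flags <- flag_unassigned(
    delta_fixture(delta),
    types = c("A", "A", "A"),
    skew_sets = list(A = integer()),
    masks_by_type = list(A = fitted),
    essential_idx = list(A = 7:10)
  )
  expect_identical(flags$misfit_count, c(4L, 3L, 1L))
  expect_equal(flags$misfit_essential_fraction, c(0, 0, 0.25))
  expect_identical(flags$unassigned, c(TRUE, FALSE, TRUE))

  # type-skewed genes are zeroed before counting
  flags2 <- flag_unassigned(
    delta_fixture(delta),
    types = c("A", "A", "A"),
    skew_sets = list(A = 1:2),
    masks_by_type = list(A = fitted),
    essential_idx = list(A = 7:10)
  )
  expect_identical(flags2$misfit_count[1:2], c(2L, 1L))
  expect_identical(flags2$unassigned[1:2], c(FALSE, FALSE))

  # a type with no essential genes contributes fraction 0
  flags3 <- flag_unassigned(
    delta_fixture(delta), c("A", "A", "A"),
    skew_sets = list(A = integer()),
    masks_by_type = list(A = fitted),
    essential_idx = list()
  )
  expect_equal(flags3$misfit_essential_fraction, c(0, 0, 0))
})

test_that("a perfectly explained metacell abandons the composite attempt", {
  withr::with_seed(2, e_a <- matrix(rnorm(6 * 30), 6, 30))
  expect_null(residual_candidates(e_a[1, ], e_a[1, ], e_a))
})

test_that("residual candidates find the second region of a two-cluster atlas", {
  # two well-separated clusters of 6 metacells each
  withr::with_seed(14, {
    c1 <- matrix(rnorm(40, mean = 0), 1, 40)[rep(1, 6), ] +
      matrix(rnorm(240, sd = 0.1), 6, 40)
    c2 <- matrix(rnorm(40, mean = 0), 1, 40)[rep(1, 6), ] +
      matrix(rnorm(240, sd = 0.1), 6, 40) + 3
  })
  e_a <- rbind(c1, c2)
  # a query sitting between the clusters, fitted first to cluster 1
  query <- 0.5 * e_a[1, ] + 0.5 * e_a[7, ]
  projected <- e_a[1, ]
  second <- residual_candidates(query, projected, e_a)
  expect_true(second$anchor %in% 7:12)
  primary <- select_candidates(1, e_a, n_closest = 6)
  expect_length(intersect(primary$members[1:6], second$members[1:6]), 0)
})

test_that("the union fit can only improve the objective", {
  withr::with_seed(15, {
    e_a <- matrix(rnorm(12 * 50), 12, 50)
    query <- 0.4 * e_a[1, ] + 0.6 * e_a[8, ]
  })
  primary <- select_candidates(1, e_a, n_closest = 4)
  secondary <- select_candidates(8, e_a, n_closest = 4)
  w_single <- solve_mixture_weights(query, e_a, primary)
  union_members <- unique(c(primary$members, secondary$members))
  cand_union <- structure(
    list(anchor = primary$anchor, members = union_members,
         distances = primary$distances),
    class = "mc_candidates"
  )
  w_union <- solve_mixture_weights(query, e_a, cand_union)
  expect_lte(solver_objective(w_union, e_a, query),
             solver_objective(w_single, e_a, query) + 1e-9)
})

test_that("doublets become composites with the correct type pair; novel states do not", {
  dp <- tibble::tibble(
    type_a = c("T01", "T02", "T01"),
    type_b = c("T03", "T04", "T04"),
    alpha = c(0.5, 0.4, 0.45)
  )
  # at least 12 metacells per type so the 10-closest candidate rule stays
  # type-pure and a doublet cannot be explained by one region
  sc <- synth_scenario(
    n_types = 5, metacells_per_type = 12, n_genes = 800,
    n_feature_genes = 200, umis_per_metacell = 50000,
    n_markers = 40, n_essential = 3, seed = 19,
    n_mixture_queries = 20, doublet_pairs = dp,
    novel_types = "T05", novel_metacells = 2
  )
  atlas <- generate_atlas(sc)
  q <- generate_query(sc, atlas)
  res <- project_query(q$query, atlas)
  truth <- q$truth$metacells

  dbl <- truth$kind == "doublet"
  got_pair <- paste(
    pmin(res$metacells$projected_type[dbl], res$metacells$composite_type[dbl]),
    pmax(res$metacells$projected_type[dbl], res$metacells$composite_type[dbl])
  )
  want_pair <- paste(pmin(truth$type_a[dbl], truth$type_b[dbl]),
                     pmax(truth$type_a[dbl], truth$type_b[dbl]))
  accepted <- res$metacells$composite_type[dbl] != ""
  expect_gte(sum(accepted & got_pair == want_pair), 2)
  # a composite never pairs a type with itself
  comp <- res$metacells$composite_type != ""
  expect_true(all(res$metacells$projected_type[comp] !=
                    res$metacells$composite_type[comp]))

  # novel metacells are not accepted as composites and stay unassigned
  nov <- truth$kind == "novel"
  expect_true(all(res$metacells$composite_type[nov] == ""))
  expect_true(all(!res$metacells$similar[nov]))

  # acceptance monotonicity: composite misfits <= single-region misfits
  single <- project_query(q$query, atlas, config = list(composite_enabled = FALSE))
  idx <- which(res$metacells$composite_type != "")
  expect_true(all(res$metacells$misfit_count[idx] <=
                    single$metacells$misfit_count[idx]))
})
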