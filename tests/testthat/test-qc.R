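# QC assembly, r2, threshold recomputation, result IO, tidy accessors.

test_that("r2 is squared Pearson over fitted genes with degenerate rules", {
  withr::with_seed(6, {
    e_q <- matrix(rnorm(3 * 5), 3, 5)
  })
  # identity: r2 = 1
  expect_equal(compute_r2(e_q, e_q), rep(1, 3))
  # constant projection: zero variance rule gives 0
  e_flat <- matrix(1, 3, 5)
  expect_equal(compute_r2(e_q, e_flat), rep(0, 3))
  # fewer than two fitted genes: 0
  expect_equal(compute_r2(e_q, e_q, fitted = c(TRUE, rep(FALSE, 4))),
               rep(0, 3))
  # toy case against the scalar oracle
  withr::with_seed(7, e_p <- e_q + matrix(rnorm(15, sd = 0.3), 3, 5))
  got <- compute_r2(e_q, e_p)
  for (i in 1:3) {
    expect_equal(got[i], oracle_pearson(e_q[i, ], e_p[i, ])^2,
                 tolerance = 1e-12)
  }
})

test_that("self-projection QC is clean and the similar mask is pure", {
  sc <- small_scenario()
  atlas <- generate_atlas(sc)
  res <- project_query(as_query(atlas), atlas)
  mc <- res$metacells
  expect_true(all(mc$similar))
  expect_true(all(mc$misfit_count == 0))
  expect_true(all(mc$r2 > 0.99))
  expect_identical(mc$projected_type, unname(atlas$types))
  # every metacell fits all feature genes on clean self-projection
  expect_true(all(mc$n_fitted == res$n_feature_common))
  # similar is recomputable from the ledger columns alone
  again <- mc$misfit_count <= res$config$max_misfit &
    mc$misfit_essential_fraction < res$config$max_essential_fraction &
    mc$n_fitted >= res$n_feature_common / 3
  expect_identical(mc$similar, again)
})

test_that("misfit QC can be recomputed at other thresholds", {
  sc <- small_scenario(n_mixture_queries = 16, novel_types = "T04")
  atlas <- generate_atlas(sc)
  q <- generate_query(sc, atlas)
  res <- project_query(q$query, atlas)

  # idempotence at the original thresholds
  same <- recompute_misfits(res)
  expect_identical(same$metacells, res$metacells)

  # an infinite threshold clears all misfits; every sufficiently fitted
  # metacell becomes similar
  loose <- recompute_misfits(res, max_lfold = Inf)
  expect_true(all(loose$metacells$misfit_count == 0))
  expect_identical(
    loose$metacells$similar,
    loose$metacells$n_fitted >= res$n_feature_common / 3
  )

  # lowering the threshold is monotone in the misfit counts
  tight <- recompute_misfits(res, max_lfold = 1)
  expect_true(all(tight$metacells$misfit_count >=
                    res$metacells$misfit_count))
})

test_that("results round-trip through write_result and read_result", {
  sc <- small_scenario(n_mixture_queries = 12, novel_types = "T04",
                       novel_metacells = 2)
  atlas <- generate_atlas(sc)
  q <- generate_query(sc, atlas)
  res <- project_query(q$query, atlas)
  dir <- withr::local_tempdir()
  write_result(res, dir)

  qc <- readr::read_tsv(file.path(dir, "metacell_qc.tsv"),
                        show_col_types = FALSE)
  expect_identical(nrow(qc), nrow(q$query$umis))

  back <- read_result(dir)
  expect_equal(as.data.frame(back$metacells), as.data.frame(res$metacells))
  expect_equal(back$gene_qc, res$gene_qc)
  expect_equal(back$weights, res$weights)
  # the weights layer keeps row sums at 1
  expect_true(all(abs(rowSums(back$weights) - 1) < 1e-9))
  # recomputation works identically on the reloaded result
  re1 <- recompute_misfits(res, max_lfold = 2)
  re2 <- recompute_misfits(back, max_lfold = 2)
  expect_equal(re2$metacells$misfit_count, re1$metacells$misfit_count)
  expect_identical(re2$metacells$similar, re1$metacells$similar)
})

test_that("tidy, glance and autoplot expose the result tables", {
  sc <- small_scenario(n_mixture_queries = 8)
  atlas <- generate_atlas(sc)
  q <- generate_query(sc, atlas)
  res <- project_query(q$query, atlas)
  expect_identical(tidy(res), res$metacells)
  expect_identical(tidy(res, "genes"), res$gene_qc)
  w <- tidy(res, "weights")
  expect_true(all(w$weight >= res$config$min_weight))
  sums <- tapply(w$weight, w$metacell, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  g <- glance(res)
  expect_identical(g$n_query, nrow(q$query$umis))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, "correction"), "ggplot")
  expect_s3_class(autoplot(res, "expression"), "ggplot")
})
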