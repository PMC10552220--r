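# Range filtering, fold deviations, type assignment and per-type skew.

test_that("range filtering drops genes with insufficient shared range", {
  # 51 values: the 2% / 98% quantiles hit the 2nd and 50th order
  # statistics exactly (no interpolation), so ranges are exact integers
  n <- 51
  span <- 0:50 # query range [1, 49], length 48
  e_q <- cbind(
    same = span,            # identical distributions: kept
    shifted = span,         # projection shifted by > half: filtered
    exact50 = span,         # shared exactly 50%: kept (strict less)
    flat = rep(2, n)        # zero query range: kept
  )
  e_p <- cbind(
    same = span,
    shifted = span + 30,
    exact50 = span + 24,    # shared [25, 49] = exactly half of 48
    flat = rep(7, n)
  )
  rf <- range_filter(e_q, e_p)
  expect_identical(unname(rf$filtered), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(unname(rf$kept), c(TRUE, FALSE, TRUE, TRUE))
  # the shared range is the intersection of the two quantile ranges
  expect_equal(unname(rf$low_shared[2]), unname(rf$low_projected[2]))
  expect_equal(unname(rf$high_shared[2]), unname(rf$high_query[2]))

  # exempt genes are never range-filtered
  rf2 <- range_filter(e_q, e_p, exempt = c(FALSE, TRUE, FALSE, FALSE))
  expect_false(rf2$filtered[2])
})

test_that("fold deviations require both the fold and the UMI-depth gates", {
  fr_q <- rbind(c(16e-4, 1e-3, 2e-5), c(1e-3, 1e-3, 1e-3))
  fr_p <- rbind(c(1e-4, 1e-3, 1e-3), c(1e-3, 1e-3, 1e-3))
  colnames(fr_q) <- colnames(fr_p) <- c("big", "same", "shallow")
  totals <- c(50000, 50000)
  dev <- compute_deviation(fr_q, fr_p, totals)
  # 16x with deep coverage: |lfold| near 4, a misfit
  expect_gt(abs(dev$lfold[1, "big"]), 3)
  expect_true(dev$delta[1, "big"])
  # identical profiles: no fold, no misfit
  expect_equal(unname(dev$lfold[1, "same"]), 0)
  expect_false(dev$delta[1, "same"])

  # a >8x fold with under 40 summed UMIs is ignored
  fr_q2 <- rbind(c(1e-3, 1e-3))
  fr_p2 <- rbind(c(1e-5, 1e-3))
  colnames(fr_q2) <- colnames(fr_p2) <- c("sparse", "x")
  dev2 <- compute_deviation(fr_q2, fr_p2, totals = 50000)
  expect_gt(abs(dev2$lfold[1, "sparse"]), 3)
  expect_true(dev2$delta[1, "sparse"])
  dev3 <- compute_deviation(fr_q2, fr_p2, totals = 50000,
                            config = list(min_umis = 40))
  expect_identical(dev3$delta, dev2$delta)
  # shrink the depth so the summed UMIs fall below the gate
  dev4 <- compute_deviation(fr_q2, fr_p2, totals = 50)
  expect_false(dev4$delta[1, "sparse"])

  # noisy/lateral genes are never negative evidence
  dev5 <- compute_deviation(fr_q, fr_p, totals, exempt = c(TRUE, FALSE, FALSE))
  expect_false(dev5$delta[1, "big"])
})

test_that("types are assigned by maximal summed weight with lexicographic ties", {
  W <- rbind(
    c(1, 0, 0, 0),
    c(0.35, 0.25, 0.4, 0),
    c(0.5, 0, 0.5, 0)
  )
  rownames(W) <- paste0("q", 1:3)
  types <- c("T-cell", "T-cell", "B-cell", "B-cell")
  got <- assign_types(W, types)
  expect_identical(unname(got[1]), "T-cell")
  expect_identical(unname(got[2]), "T-cell") # 0.6 vs 0.4
  expect_identical(unname(got[3]), "B-cell") # tie: lexicographically first
})

test_that("skew needs strictly more than half of the type's metacells", {
  delta <- rbind(
    c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, FALSE),
    c(FALSE, TRUE), c(FALSE, FALSE)
  )
  colnames(delta) <- c("g1", "g2")
  types <- c("A", "A", "A", "A", "B", "B")
  sk <- detect_type_skew(delta, types)
  expect_equal(sk$skew["A", "g1"], 0.75)
  expect_equal(sk$skew["A", "g2"], 0.5)
  expect_identical(sk$skewed_genes$A, c(g1 = 1L)) # 0.5 is NOT skewed
  expect_equal(sk$skew["B", "g2"], 0.5)
  expect_length(sk$skewed_genes$B, 0)

  # scalar per-type means computed independently
  for (t in c("A", "B")) {
    for (g in 1:2) {
      expect_equal(sk$skew[t, g], mean(delta[types == t, g]))
    }
  }
})

test_that("a contaminated gene is quarantined per type without global loss", {
  sc <- small_scenario(n_mixture_queries = 24)
  atlas <- generate_atlas(sc)
  q <- generate_query(sc, atlas)
  # inject ambient-like contamination of one feature gene into the
  # metacells of one type: bump its counts 30-fold
  gene <- atlas$masks$feature[1]
  u <- q$query$umis
  victims <- which(q$truth$metacells$true_type == "T01")
  u[victims, gene] <- u[victims, gene] * 30 + 500
  res <- project_query(query_model(u), atlas)
  g <- match(gene, res$genes)
  expect_true(g %in% res$skew_sets[["T01"]])
  # the gene leaves T01's fitted mask but stays fitted for other types
  expect_false(res$masks_by_type[["T01"]][g])
  expect_true(res$masks_by_type[["T03"]][g])
  # with the contaminated gene quarantined, the victims remain similar
  expect_true(all(res$metacells$similar[victims]))
})
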