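test_that("label Gaussians use denominator n, with shrinkage toward the
           scaled identity", {
  ds <- embedded_dataset("G", rbind(c(0, 0), c(2, 0)), c(0L, 0L), "fix")
  g <- fit_label_gaussians(ds, shrinkage = 0)
  expect_named(g, "0")
  expect_equal(g[["0"]]$mean, c(0, 0) + c(1, 0))
  expect_equal(g[["0"]]$covariance, matrix(c(1, 0, 0, 0), 2))
  # single-sample class: zero covariance before the absolute floor
  ds1 <- embedded_dataset("G1", rbind(c(1, 2), c(0, 0)), c(1L, 0L), "fix")
  g1 <- fit_label_gaussians(ds1, shrinkage = 0.5)
  expect_equal(g1[["1"]]$mean, c(1, 2))
  expect_equal(g1[["1"]]$covariance, matrix(0, 2, 2))  # trace is 0
  gf <- fit_label_gaussians(ds1, shrinkage = 0, floor = 1e-8)
  expect_equal(gf[["1"]]$covariance, 1e-8 * diag(2))
  expect_error(embedded_dataset("E", matrix(0, 0, 2), integer(), "fix"),
               "empty")
})

test_that("Gaussian 2-Wasserstein matches hand-computable cases", {
  g1 <- gmodel(0, 1); g2 <- gmodel(3, 1)
  expect_equal(wasserstein2_gaussians(g1, g1), 0)
  expect_equal(wasserstein2_gaussians(g1, g2), 3)          # equal variances
  expect_equal(wasserstein2_gaussians(gmodel(0, 1), gmodel(0, 9)), 2)
  # commuting covariances: sqrt(tr(I + diag(4,1) - 2 diag(2,1))) = 1
  expect_equal(wasserstein2_gaussians(gmodel(c(0, 0), diag(2)),
                                      gmodel(c(0, 0), diag(c(4, 1)))), 1)
  expect_error(wasserstein2_gaussians(g1, gmodel(c(0, 0), diag(2))),
               "dimension mismatch")
  expect_error(wasserstein2_gaussians(gmodel(NaN, 1), g1), "non-finite")
})

test_that("ground cost adds squared feature distance and squared label W2", {
  dsA <- embedded_dataset("A", matrix(0, 1, 1), 0L, "fix")
  dsB <- embedded_dataset("B", matrix(1, 1, 1), 0L, "fix")
  W0 <- matrix(0, 1, 1, dimnames = list("0", "0"))
  expect_equal(ground_cost_matrix(dsA, dsA, W0), matrix(0, 1, 1))
  W1 <- matrix(1, 1, 1, dimnames = list("0", "0"))
  expect_equal(ground_cost_matrix(dsA, dsB, W1), matrix(2, 1, 1))
  # identical features, labels differing with W2 = w -> cross entries w^2
  dsC <- embedded_dataset("C", rbind(0, 0), c(0L, 1L), "fix")
  W <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("0", "1"), c("0", "1")))
  gc <- ground_cost_matrix(dsC, dsC, W)
  expect_equal(gc, matrix(c(0, 9, 9, 0), 2))
  expect_error(ground_cost_matrix(dsC, dsC, W0), "missing a label pair")
})

test_that("exact OT solves trivial and enumerable instances", {
  p1 <- solve_exact_ot(matrix(5, 1, 1))
  expect_equal(p1$plan, matrix(1, 1, 1))
  expect_equal(p1$cost, 5)
  p2 <- solve_exact_ot(matrix(c(0, 1, 1, 0), 2))
  expect_equal(p2$cost, 0)
  expect_equal(p2$plan, diag(0.5, 2))
  set.seed(11)
  for (r in 1:60) {
    n <- sample(2:5, 1)
    C <- matrix(runif(n * n), n)
    expect_lt(abs(solve_exact_ot(C)$cost - brute_force_ot(C)), 1e-9)
  }
})

test_that("exact OT agrees with the Hungarian assignment oracle", {
  skip_if_not_installed("clue")
  set.seed(12)
  for (r in 1:5) {
    n <- sample(6:15, 1)
    C <- matrix(runif(n * n), n)
    lsap <- clue::solve_LSAP(C)
    oracle <- sum(C[cbind(seq_len(n), as.integer(lsap))]) / n
    expect_equal(solve_exact_ot(C)$cost, oracle, tolerance = 1e-9)
  }
})

test_that("exact OT handles rectangular problems and enforces marginals", {
  set.seed(13)
  C <- matrix(runif(12 * 7), 12, 7)
  p <- solve_exact_ot(C)
  expect_equal(rowSums(p$plan), rep(1 / 12, 12), tolerance = 1e-6)
  expect_equal(colSums(p$plan), rep(1 / 7, 7), tolerance = 1e-6)
  expect_true(all(p$plan >= -1e-12))
  expect_equal(p$cost, sum(p$plan * C), tolerance = 1e-12)
  expect_error(solve_exact_ot(C, a = rep(1, 12)), "sum to 1")
  expect_error(solve_exact_ot(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("Sinkhorn approaches the exact optimum as epsilon shrinks", {
  expect_equal(solve_sinkhorn(matrix(3, 2, 2), epsilon = 1)$cost, 3)
  set.seed(14)
  C <- matrix(c(0, 1, 1, 0), 2)
  costs <- vapply(c(1, 0.1, 0.01), function(eps)
    solve_sinkhorn(C, epsilon = eps)$cost, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_lt(costs[3], 0.01)
  # marginal contract and cost >= exact on random instances
  for (r in 1:5) {
    C <- matrix(runif(100), 10)
    ex <- solve_exact_ot(C)$cost
    sk <- solve_sinkhorn(C, epsilon = 0.05 * mean(C), tol = 1e-9)
    expect_true(sk$converged)
    expect_lt(max(abs(rowSums(sk$plan) - 1 / 10)), 1e-9)
    expect_gte(sk$cost, ex - 1e-12)
  }
  set.seed(99)
  expect_warning(solve_sinkhorn(matrix(runif(400), 20), epsilon = 1e-3,
                                max_iter = 5L), "did not reach")
})

test_that("otdd_distance is a pseudometric that solves the worked
           singleton case", {
  cfg0 <- otdd_config(covariance_shrinkage = 0, covariance_floor = 0)
  A <- embedded_dataset("A", matrix(0, 1, 1), 0L, "fix")
  B <- embedded_dataset("B", matrix(1, 1, 1), 0L, "fix")
  # degenerate Gaussians at 0 and 1: label W2 = 1, cost = 1 + 1, d = sqrt(2)
  expect_equal(otdd_distance(A, B, cfg0), sqrt(2), tolerance = 1e-12)
  set.seed(15)
  for (r in 1:10) {
    D1 <- make_gaussian_ds("D1", n = 14, seed = r)
    D2 <- make_gaussian_ds("D2", n = 10, sep = 0.5, seed = r + 100)
    expect_lt(otdd_distance(D1, D1), 1e-8)
    d12 <- otdd_distance(D1, D2); d21 <- otdd_distance(D2, D1)
    expect_gte(d12, 0)
    expect_lt(abs(d12 - d21), 1e-8)
  }
  expect_error(otdd_distance(A, make_gaussian_ds(featurizer = "other")),
               "featurizer mismatch")
})

test_that("otdd_distance is homogeneous under joint feature scaling", {
  cfg0 <- otdd_config(covariance_shrinkage = 0, covariance_floor = 0)
  set.seed(16)
  D1 <- make_gaussian_ds("D1", n = 12, seed = 1)
  D2 <- make_gaussian_ds("D2", n = 12, sep = 1, seed = 2)
  d <- otdd_distance(D1, D2, cfg0)
  for (s in c(0.5, 3)) {
    D1s <- embedded_dataset("D1", s * D1$features, D1$labels, "fix")
    D2s <- embedded_dataset("D2", s * D2$features, D2$labels, "fix")
    expect_equal(otdd_distance(D1s, D2s, cfg0), s * d, tolerance = 1e-8)
  }
})

test_that("stratified subsampling caps task size and is seeded", {
  big <- make_gaussian_ds("BIG", n = 300, seed = 3)
  cfg <- otdd_config(max_samples_per_task = 40, seed = 9)
  d1 <- otdd_distance(big, make_gaussian_ds("O", n = 30, seed = 4), cfg)
  d2 <- otdd_distance(big, make_gaussian_ds("O", n = 30, seed = 4), cfg)
  expect_identical(d1, d2)
})

test_that("chem_distance_matrix matches pairwise calls and caches", {
  s1 <- make_gaussian_ds("S1", n = 12, seed = 5)
  s2 <- make_gaussian_ds("S2", n = 12, sep = 0, seed = 6)
  t1 <- make_gaussian_ds("T1", n = 12, sep = 1, seed = 7)
  cfg <- otdd_config()
  dm <- chem_distance_matrix(list(s1, s2), list(t1), cfg)
  expect_identical(dim(dm$values), c(2L, 1L))
  expect_equal(dm$values["S1", "T1"], otdd_distance(s1, t1, cfg))
  expect_equal(dm$values["S2", "T1"], otdd_distance(s2, t1, cfg))
  # duplicated source -> identical rows
  s1b <- embedded_dataset("S1b", s1$features, s1$labels, "fix")
  dm2 <- chem_distance_matrix(list(s1, s1b), list(t1), cfg)
  expect_equal(unname(dm2$values[1, ]), unname(dm2$values[2, ]))
  # caching: a second run reads pair results instead of recomputing
  cache <- withr::local_tempdir()
  chem_distance_matrix(list(s1), list(t1), cfg, cache_dir = cache)
  f <- list.files(cache, full.names = TRUE)
  expect_length(f, 1L)
  writeLines("123.5", f)  # poison the cache: a rerun must read, not solve
  dm3 <- chem_distance_matrix(list(s1), list(t1), cfg, cache_dir = cache)
  expect_equal(unname(dm3$values[1, 1]), 123.5)
})
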