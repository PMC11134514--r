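test_that("knn_hardness matches hand values and the sort-and-average
           oracle", {
  expect_equal(knn_hardness(c(a = 5, b = 2, c = 9), k = 1), 2)
  expect_equal(knn_hardness(c(a = 1, b = 2, c = 3), k = 3), 2)
  expect_equal(knn_hardness(c(a = 1, b = 2, c = 3), k = 3,
                            weights = c(a = 1, b = 1, c = 2)),
               (1 + 2 + 6) / 4)
  # ties break by ascending source id
  expect_equal(knn_hardness(c(z = 1, a = 1, m = 5), k = 1), 1)
  tied <- c(z = 1, a = 1)
  expect_equal(knn_hardness(tied, k = 1, weights = c(z = 10, a = 1)),
               1)  # the id decides which neighbor, value unchanged here
  expect_error(knn_hardness(c(1, 2), k = 0), "k must be")
  expect_error(knn_hardness(c(1, 2), k = 3), "exceeds")
  expect_error(knn_hardness(c(a = 1, b = 2), k = 2,
                            weights = c(a = -1, b = 1)), "negative")
  set.seed(31)
  for (r in 1:200) {
    n <- 50
    col <- setNames(runif(n), sprintf("S%03d", sample(n)))
    k <- sample(n, 1)
    w <- setNames(runif(n), names(col))
    expect_equal(knn_hardness(col, k), knn_oracle(col, k))
    expect_equal(knn_hardness(col, k, w), knn_oracle(col, k, w))
    # uniform weights reduce to the plain mean
    u <- setNames(rep(2, n), names(col))
    expect_equal(knn_hardness(col, k, u), knn_hardness(col, k))
  }
})

test_that("mean over the k smallest distances is non-decreasing in k", {
  set.seed(32)
  col <- setNames(runif(30), sprintf("S%02d", 1:30))
  vals <- vapply(1:30, function(k) knn_hardness(col, k), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("min-max normalization hits [0,1] with attained endpoints", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  set.seed(33)
  for (r in 1:20) {
    v <- rnorm(sample(2:30, 1))
    if (max(v) == min(v)) next
    out <- minmax_normalize(v)
    expect_equal(min(out), 0)
    expect_equal(max(out), 1)
  }
  expect_error(minmax_normalize(c(1, NA)), "non-finite")
  expect_error(minmax_normalize(numeric()), "empty")
})

test_that("internal hardness calibrates: separable near 0, permuted
           near 1/2", {
  sep_task <- synthetic_classification_task(n = 200, seed = 1)
  h_sep <- vapply(1:5, function(s)
    internal_hardness(sep_task, cfg = hardness_config(), seed = s),
    numeric(1))
  expect_lte(median(h_sep), 0.05)
  null_task <- permute_labels(sep_task, seed = 2)
  h_null <- vapply(1:5, function(s)
    internal_hardness(null_task, cfg = hardness_config(), seed = s),
    numeric(1))
  expect_lt(abs(median(h_null) - 0.5), 0.12)
  # knn model path works and calibrates too
  h_knn <- internal_hardness(sep_task,
                             cfg = hardness_config(int_model = "knn"))
  expect_lte(h_knn, 0.1)
})

test_that("internal hardness rejects degenerate tasks", {
  all_active <- bioactivity_task("AA", paste0("M", 1:40), rep(1L, 40),
                                 features = matrix(rnorm(80), 40))
  expect_error(internal_hardness(all_active), "single class")
  tiny <- make_gaussian_ds(n = 10)
  expect_error(internal_hardness(tiny, cfg = hardness_config(m_train = 16)),
               "too small")
})

test_that("scaffold split trains on the largest scaffolds", {
  ds <- make_gaussian_ds(n = 64, seed = 5)
  scaf <- rep(c("big", "mid", "s1", "s2"), c(40, 16, 4, 4))
  sp <- taskhardness:::.split_task(ds$labels, 16L, "scaffold", 1,
                                   scaffolds = scaf)
  expect_true(all(scaf[sp$train] == "big"))
  expect_length(sp$train, 16L)
  expect_error(taskhardness:::.split_task(ds$labels, 16L, "scaffold", 1),
               "scaffold key")
})

test_that("source difficulty weights mirror internal hardness", {
  sep <- synthetic_classification_task(n = 120, seed = 11, task_id = "EASY")
  hard <- permute_labels(
    synthetic_classification_task(n = 120, seed = 12, task_id = "HARD"),
    seed = 3)
  w <- source_difficulty_weights(list(sep, hard))
  expect_lte(w[["EASY"]], 0.15)
  expect_gt(w[["HARD"]], 0.3)
  # identical sources get identical weights under the shared seed
  sep2 <- sep; sep2$task_id <- "EASY2"
  w2 <- source_difficulty_weights(list(sep, sep2))
  expect_equal(unname(w2["EASY"]), unname(w2["EASY2"]))
  # failing sources fall back to the mean weight of the successes
  degen <- bioactivity_task("DEG", paste0("M", 1:30), rep(1L, 30),
                            features = matrix(rnorm(60), 30))
  expect_message(w3 <- source_difficulty_weights(list(sep, degen)),
                 "mean weight")
  expect_equal(unname(w3["DEG"]), unname(w3["EASY"]))
})

test_that("compute_hardness combines normalized components as configured", {
  sid <- paste0("S", 1:4); tid <- paste0("T", 1:3)
  chem <- distance_matrix(matrix(c(1, 2, 3, 4,
                                   5, 6, 7, 8,
                                   1, 1, 1, 1), 4, 3),
                          sid, tid, "chem")
  prot <- distance_matrix(matrix(c(2, 2, 2, 2,
                                   1, 3, 5, 7,
                                   4, 4, 4, 4), 4, 3),
                          sid, tid, "prot")
  cfg <- hardness_config(k = 2, ext_chem_weighting = "plain",
                         weights = c(1, 1, 0))
  rep1 <- compute_hardness(chem, prot, cfg = cfg)
  expect_identical(rep1$task_id, tid)
  # raw EXT_CHEM: means of the 2 smallest entries per column
  expect_equal(rep1$ext_chem_raw, c(1.5, 5.5, 1))
  expect_equal(rep1$ext_prot_raw, c(2, 2, 4))
  expect_true(all(is.na(rep1$int_chem_raw)))
  expect_equal(rep1$ext_chem_norm, (c(1.5, 5.5, 1) - 1) / 4.5)
  expect_equal(rep1$combined,
               rep1$ext_chem_norm + rep1$ext_prot_norm)
  # zero weight on a component leaves the combination unaffected by it
  cfg2 <- hardness_config(k = 2, ext_chem_weighting = "plain",
                          weights = c(1, 0, 0))
  rep2 <- compute_hardness(chem, prot, cfg = cfg2)
  expect_equal(rep2$combined, rep1$ext_chem_norm)
  expect_equal(sort(rep2$combined), c(0, 1 / 9, 1))
  # constant components across targets give combined = 0 everywhere
  const <- distance_matrix(matrix(1, 4, 3), sid, tid, "chem")
  rep3 <- compute_hardness(const, const, cfg = cfg)
  expect_equal(rep3$combined, c(0, 0, 0))
  # a target missing from a required matrix is an error
  chem_miss <- distance_matrix(chem$values[, 1:2], sid, tid[1:2], "chem")
  tgt_stub <- lapply(tid, function(id) bioactivity_task(id, "M1", 0L))
  expect_error(compute_hardness(chem_miss, prot, targets = tgt_stub,
                                cfg = cfg),
               "absent from the chemical")
})

test_that("compute_hardness is invariant to target order", {
  set.seed(34)
  sid <- paste0("S", 1:6); tid <- paste0("T", 1:4)
  chem <- distance_matrix(matrix(runif(24), 6), sid, tid, "chem")
  prot <- distance_matrix(matrix(runif(24), 6), sid, tid, "prot")
  cfg <- hardness_config(k = 3, ext_chem_weighting = "plain",
                         weights = c(1, 1, 0))
  r1 <- compute_hardness(chem, prot, cfg = cfg)
  perm <- c(3, 1, 4, 2)
  chem_p <- distance_matrix(chem$values[, perm], sid, tid[perm], "chem")
  prot_p <- distance_matrix(prot$values[, perm], sid, tid[perm], "prot")
  r2 <- compute_hardness(chem_p, prot_p, cfg = cfg)
  expect_equal(r2$combined[match(r1$task_id, r2$task_id)], r1$combined)
})

test_that("hardness reports round-trip with provenance", {
  dir <- withr::local_tempdir()
  sid <- paste0("S", 1:4); tid <- paste0("T", 1:3)
  chem <- distance_matrix(matrix(runif(12), 4), sid, tid, "chem")
  prot <- distance_matrix(matrix(runif(12), 4), sid, tid, "prot")
  cfg <- hardness_config(k = 2, ext_chem_weighting = "plain",
                         weights = c(1, 1, 0))
  rep1 <- compute_hardness(chem, prot, cfg = cfg)
  p <- file.path(dir, "hardness.csv")
  write_hardness_report(rep1, p)
  back <- read_hardness_report(p)
  expect_equal(back$combined, rep1$combined, tolerance = 1e-12)
  expect_equal(attr(back, "provenance")$k, 2)
})

test_that("source selection ranks by the requested criterion", {
  sid <- c("S1", "S2", "S3"); tid <- "T1"
  chem <- distance_matrix(matrix(c(0.3, 0.1, 0.2), 3, 1), sid, tid, "chem")
  prot <- distance_matrix(matrix(c(5, 9, 1), 3, 1), sid, tid, "prot")
  expect_identical(select_source_tasks("T1", chem, prot, k = 3,
                                       criterion = "chem"),
                   c("S2", "S3", "S1"))
  expect_identical(select_source_tasks("T1", chem, prot, k = 1,
                                       criterion = "prot"), "S3")
  # sum_norm tie broken by ascending id: chem [0,1], prot [1,0] -> both 1
  chem2 <- distance_matrix(matrix(c(0, 1), 2, 1), c("S1", "S2"), tid,
                           "chem")
  prot2 <- distance_matrix(matrix(c(1, 0), 2, 1), c("S1", "S2"), tid,
                           "prot")
  expect_identical(select_source_tasks("T1", chem2, prot2, k = 2),
                   c("S1", "S2"))
  expect_error(select_source_tasks("T1", chem, prot, k = 4), "exceeds")
  expect_error(select_source_tasks("T9", chem, prot, k = 1,
                                   criterion = "chem"), "absent")
})
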