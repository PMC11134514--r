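test_that("episodes are stratified, disjoint and reproducible", {
  ds <- make_gaussian_ds(n = 200, seed = 41)
  ep <- build_episode(ds, support_size = 16, seed = 1)
  expect_identical(nrow(ep$support_features), 16L)
  expect_identical(nrow(ep$query_features), 184L)
  expect_setequal(unique(ep$support_labels), c(0L, 1L))
  ep2 <- build_episode(ds, support_size = 16, seed = 1)
  expect_identical(ep, ep2)
  ep3 <- build_episode(ds, support_size = 16, seed = 2)
  expect_false(identical(ep$support_features, ep3$support_features))
  expect_error(build_episode(ds, support_size = 200, seed = 1),
               "support_size")
})

test_that("prototypes are class means", {
  X <- rbind(c(0, 0), c(2, 2), c(10, 0))
  pr <- compute_prototypes(X, c(0L, 0L, 1L))
  expect_equal(pr$prototypes["0", ], c(1, 1))
  expect_equal(pr$prototypes["1", ], c(10, 0))
  X3 <- rbind(c(1, 0), c(3, 0), c(5, 3), c(0, 0))
  pr3 <- compute_prototypes(X3, c(0L, 0L, 0L, 1L))
  expect_equal(pr3$prototypes["0", ], c(3, 1))
  expect_error(compute_prototypes(X, c(0L, 0L, 0L)), "single class")
})

test_that("query classification is a softmax over negative squared
           distances", {
  pr <- compute_prototypes(rbind(c(0, 0), c(4, 0)), c(0L, 1L))
  p_mid <- classify_query(rbind(c(2, 5)), pr)   # equidistant
  expect_equal(unname(p_mid[1, ]), c(0.5, 0.5))
  expect_equal(rowSums(p_mid), 1)
  p_at <- classify_query(rbind(c(0, 0)), pr)
  expect_gt(p_at[1, "0"], 0.999)
  # hand softmax: squared distances (1, 3) -> softmax(-1, -3) =
  # (0.8808, 0.1192); query at 0, prototypes at 1 and sqrt(3) in 1-D
  pr13 <- structure(list(prototypes = matrix(c(1, sqrt(3)), 2, 1,
                                             dimnames = list(c("0", "1"),
                                                             NULL)),
                         counts = c(1L, 1L)),
                    class = "prototype_set")
  got <- classify_query(matrix(0, 1, 1), pr13)
  expect_equal(unname(got[1, "0"]), 0.8808, tolerance = 1e-4)
  expect_equal(unname(got[1, "1"]), 0.1192, tolerance = 1e-4)
  expect_equal(unname(got[1, "0"]), 1 / (1 + exp(-2)), tolerance = 1e-9)
  # permutation equivariance in class order
  prA <- compute_prototypes(rbind(c(0, 0), c(3, 1)), c(0L, 1L))
  prB <- structure(list(prototypes = prA$prototypes[2:1, ],
                        counts = prA$counts[2:1]), class = "prototype_set")
  set.seed(43)
  Q <- matrix(rnorm(10), 5, 2)
  expect_equal(classify_query(Q, prA)[, c("0", "1")],
               classify_query(Q, prB)[, c("0", "1")])
  expect_error(classify_query(matrix(0, 1, 3), prA), "dimension mismatch")
})

test_that("identity encoder reduces the protonet to nearest-class-centroid
           softmax", {
  enc <- train_protonet(list(make_gaussian_ds("A", seed = 1),
                             make_gaussian_ds("B", seed = 2)),
                        encoder_cfg = encoder_config(hidden = integer(),
                                                     steps = 0L),
                        seed = 1)
  expect_true(enc$identity)
  ds <- make_gaussian_ds(n = 60, seed = 44)
  ep <- build_episode(ds, support_size = 16, seed = 3)
  Es <- encode(enc, ep$support_features)
  expect_identical(Es, ep$support_features)
  probs <- classify_query(encode(enc, ep$query_features),
                          compute_prototypes(Es, ep$support_labels))
  raw <- classify_query(ep$query_features,
                        compute_prototypes(ep$support_features,
                                           ep$support_labels))
  expect_equal(probs, raw)
  # with the full class sets as support, prototypes equal raw class means
  pr <- compute_prototypes(encode(enc, ds$features), ds$labels)
  expect_equal(pr$prototypes["1", ],
               colMeans(ds$features[ds$labels == 1L, ]))
})

test_that("episodic training reduces the loss and is deterministic", {
  set.seed(45)
  srcs <- lapply(1:4, function(i)
    make_gaussian_ds(paste0("S", i), n = 80, d = 6, sep = 4, seed = i))
  cfg <- encoder_config(hidden = c(32L), out_dim = 8L, steps = 120L)
  enc1 <- train_protonet(srcs, encoder_cfg = cfg, seed = 7)
  tr <- attr(enc1, "loss_trace")
  expect_lt(mean(tail(tr, 20)), mean(head(tr, 20)))
  enc2 <- train_protonet(srcs, encoder_cfg = cfg, seed = 7)
  expect_identical(enc1$layers, enc2$layers)
  expect_error(train_protonet(srcs[1], encoder_cfg = cfg), "at least 2")
})

test_that("evaluation calibrates on separable and random-label tasks", {
  sep <- make_gaussian_ds("SEP", n = 150, d = 6, sep = 6, seed = 46)
  r_rf <- evaluate_task("rf", sep, support_size = 16, n_seeds = 3, seed = 1)
  expect_gte(r_rf$roc_auc, 0.95)
  id_enc <- train_protonet(list(sep, sep), encoder_cfg =
                             encoder_config(hidden = integer(), steps = 0L))
  r_pn <- evaluate_task("protonet", sep, support_size = 16,
                        encoder = id_enc, n_seeds = 3, seed = 1)
  expect_gte(r_pn$roc_auc, 0.95)
  set.seed(47)
  null_ds <- embedded_dataset("NULL", matrix(rnorm(150 * 6), 150),
                              sample(rep(0:1, 75)), "fix")
  r_null <- evaluate_task("rf", null_ds, support_size = 16, n_seeds = 5,
                          seed = 1)
  expect_lt(abs(r_null$roc_auc - 0.5), 0.12)
  expect_error(evaluate_task("protonet", sep), "requires a trained encoder")
})

test_that("rf evaluation ties to the internal-hardness pathway on the same
           split and seed", {
  ds <- make_gaussian_ds("TIE", n = 120, d = 5, sep = 2, seed = 48)
  cfg <- hardness_config(m_train = 16L)
  # same base seed: build_episode uses seed + 1000 for its first draw
  rec <- evaluate_task("rf", ds, support_size = 16, n_seeds = 1, seed = 5,
                       cfg = cfg)
  h <- internal_hardness(ds, cfg = cfg, seed = 5 + 1000L)
  expect_equal(rec$roc_auc, 1 - h, tolerance = 1e-12)
})

test_that("average precision matches a hand-enumerated fixture", {
  # ranked by score: labels 1,0,1 -> precisions at positives 1 and 2/3
  expect_equal(taskhardness:::.auprc(c(1L, 0L, 1L), c(0.9, 0.5, 0.3)),
               mean(c(1, 2 / 3)))
  expect_equal(taskhardness:::.auprc(c(0L, 1L), c(0.2, 0.9)), 1)
})

test_that("hardness-gain correlation recovers exact and hand-computed
           values", {
  rep_df <- structure(
    data.frame(task_id = paste0("T", 1:4),
               combined = c(0.1, 0.4, 0.7, 1.0)),
    class = c("hardness_report", "data.frame"))
  rec <- function(id, m, v) structure(
    list(task_id = id, method = m, support_size = 16L,
         roc_auc = v, auprc = v, n_episodes = 1L, seed = 1L),
    class = "eval_record")
  meta <- Map(rec, paste0("T", 1:4), "protonet",
              0.5 - c(0.1, 0.4, 0.7, 1.0))
  base <- Map(rec, paste0("T", 1:4), "rf", rep(0.5, 4))
  out <- hardness_gain_correlation(rep_df, meta, base)
  expect_equal(out$pearson, -1)
  expect_equal(out$spearman, -1)
  # hand 4-point fixture, Pearson by the closed formula
  gains <- c(0.2, 0.05, 0.1, -0.15)
  meta2 <- Map(rec, paste0("T", 1:4), "protonet", 0.5 + gains)
  out2 <- hardness_gain_correlation(rep_df, meta2, base)
  h <- c(0.1, 0.4, 0.7, 1.0)
  hand <- sum((h - mean(h)) * (gains - mean(gains))) /
    sqrt(sum((h - mean(h))^2) * sum((gains - mean(gains))^2))
  expect_equal(out2$pearson, hand, tolerance = 1e-12)
  const <- Map(rec, paste0("T", 1:4), "protonet", rep(0.5, 4))
  expect_error(hardness_gain_correlation(rep_df, const, const),
               "zero variance")
  expect_error(hardness_gain_correlation(rep_df[1:2, ], meta[1:2],
                                         base[1:2]), ">= 3 targets")
})
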