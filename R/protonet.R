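#' Build a support/query episode from a task
#'
#' Draws a stratified support set of `support_size` molecules; the remainder
#' of the task is the query set. Reproducible under `seed`; if a draw leaves
#' a class empty on either side, up to 10 reseeded draws are attempted.
#'
#' @param task A [bioactivity_task()] or [embedded_dataset()].
#' @param featurizer Featurizer for tasks.
#' @param support_size Number of support molecules (16, 32, 64 or 128 in the
#'   usual few-shot settings; any value < n - 1 is accepted).
#' @param seed Integer seed.
#' @return Object of class `episode` with support/query features and labels.
#' @export
build_episode <- function(task, featurizer = "loaded", support_size, seed) {
  ds <- if (inherits(task, "embedded_dataset")) task
  else featurize_molecules(task, featurizer)
  n <- nrow(ds$features)
  if (n < support_size + 2L)
    stop("task '", ds$task_id, "': ", n, " molecules cannot support an ",
         "episode with support_size = ", support_size)
  sp <- .split_task(ds$labels, support_size, "stratified", seed)
  structure(list(task_id = ds$task_id,
                 support_features = ds$features[sp$train, , drop = FALSE],
                 support_labels = ds$labels[sp$train],
                 query_features = ds$features[sp$valid, , drop = FALSE],
                 query_labels = ds$labels[sp$valid],
                 support_size = as.integer(support_size),
                 seed = as.integer(seed)),
            class = "episode")
}

#' Class prototypes in encoder space
#'
#' Each class prototype is the arithmetic mean of the embedded support
#' samples of that class.
#'
#' @param embedded_support Numeric matrix (s x p) of encoded support samples.
#' @param labels Binary vector of support labels; both classes must be
#'   present.
#' @return Object of class `prototype_set`: `prototypes` (one row per class,
#'   rownames = class) and `counts`.
#' @export
compute_prototypes <- function(embedded_support, labels) {
  embedded_support <- as.matrix(embedded_support)
  labs <- sort(unique(labels))
  if (length(labs) < 2L) stop("support set has a single class")
  P <- t(vapply(labs, function(l)
    colMeans(embedded_support[labels == l, , drop = FALSE]),
    numeric(ncol(embedded_support))))
  rownames(P) <- as.character(labs)
  if (any(!is.finite(P))) stop("non-finite prototype")
  structure(list(prototypes = P,
                 counts = as.integer(table(factor(labels, levels = labs)))),
            class = "prototype_set")
}

#' Classify query samples against prototypes
#'
#' Class probabilities are the softmax over negative squared Euclidean
#' distances from each embedded query sample to each prototype.
#'
#' @param embedded_query Numeric matrix (q x p).
#' @param prototypes A [compute_prototypes()] result.
#' @return Matrix (q x n_classes) of probabilities; rows sum to 1, columns
#'   named by class.
#' @export
classify_query <- function(embedded_query, prototypes) {
  embedded_query <- as.matrix(embedded_query)
  P <- prototypes$prototypes
  if (ncol(embedded_query) != ncol(P))
    stop("dimension mismatch: query ", ncol(embedded_query),
         " vs prototypes ", ncol(P))
  D <- .cpp_sqeuclidean(embedded_query, P)
  Z <- -D
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  probs <- E / rowSums(E)
  colnames(probs) <- rownames(P)
  probs
}

#' Encoder configuration
#'
#' A small feed-forward encoder mapping molecule features into the metric
#' space of the prototypical network. With `hidden = integer(0)` and
#' `steps = 0` the encoder is the identity map and the prototypical network
#' reduces to a nearest-class-centroid classifier with softmax probabilities.
#'
#' @param hidden Integer vector of hidden-layer widths (default
#'   `c(128, 128)`; ReLU activations).
#' @param out_dim Output (metric-space) dimension, default 64.
#' @param steps Training steps (episodes), default 3000 — enough for the
#'   episode loss to plateau on desk-scale universes.
#' @param lr Adam learning rate.
#' @param support_size,query_size Episode sizes during training.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(hidden = c(128L, 128L), out_dim = 64L,
                           steps = 3000L, lr = 1e-3,
                           support_size = 16L, query_size = 32L) {
  structure(list(hidden = as.integer(hidden), out_dim = as.integer(out_dim),
                 steps = as.integer(steps), lr = lr,
                 support_size = as.integer(support_size),
                 query_size = as.integer(query_size)),
            class = "encoder_config")
}

.init_encoder <- function(in_dim, cfg) {
  dims <- c(in_dim, cfg$hidden,
            if (length(cfg$hidden)) cfg$out_dim else in_dim)
  identity_map <- length(cfg$hidden) == 0L
  layers <- list()
  if (!identity_map) {
    for (l in seq_len(length(dims) - 1L)) {
      fan_in <- dims[l]
      layers[[l]] <- list(
        W = matrix(rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                   fan_in, dims[l + 1L]),
        b = numeric(dims[l + 1L]))
    }
  }
  structure(list(layers = layers, in_dim = in_dim,
                 identity = identity_map),
            class = "protonet_encoder")
}

#' Apply an encoder to a feature matrix
#'
#' @param encoder A `protonet_encoder` (from [train_protonet()]).
#' @param X Numeric matrix (n x in_dim).
#' @return Encoded matrix.
#' @export
encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "protonet_encoder"))
  X <- as.matrix(X)
  if (encoder$identity) return(X)
  H <- X
  nl <- length(encoder$layers)
  for (l in seq_len(nl)) {
    H <- sweep(H %*% encoder$layers[[l]]$W, 2, encoder$layers[[l]]$b, "+")
    if (l < nl) H <- pmax(H, 0)
  }
  H
}

# forward pass keeping intermediates for backprop
.forward_cache <- function(encoder, X) {
  H <- list(X)
  Z <- list()
  nl <- length(encoder$layers)
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(H[[l]] %*% encoder$layers[[l]]$W, 2,
                    encoder$layers[[l]]$b, "+")
    H[[l + 1L]] <- if (l < nl) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(H = H, Z = Z)
}

# gradient of mean episode cross-entropy wrt encoder parameters
.episode_grad <- function(encoder, Xs, ys, Xq, yq) {
  ns <- nrow(Xs); nq <- nrow(Xq)
  X <- rbind(Xs, Xq)
  fc <- .forward_cache(encoder, X)
  E <- fc$H[[length(fc$H)]]
  Es <- E[seq_len(ns), , drop = FALSE]
  Eq <- E[ns + seq_len(nq), , drop = FALSE]
  labs <- sort(unique(ys))
  C <- t(vapply(labs, function(l)
    colMeans(Es[ys == l, , drop = FALSE]), numeric(ncol(E))))
  D <- .cpp_sqeuclidean(Eq, C)
  Z <- -D
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  Y <- outer(yq, labs, "==") * 1
  loss <- -mean(log(pmax(P[Y == 1], 1e-12)))
  G <- (P - Y) / nq                       # d loss / d logits
  dEq <- 2 * (G %*% C)                    # rows of G sum to 0
  dC <- 2 * (t(G) %*% Eq - diag(colSums(G), nrow = length(labs)) %*% C)
  dEs <- matrix(0, ns, ncol(E))
  for (i in seq_along(labs)) {
    rows <- which(ys == labs[i])
    dEs[rows, ] <- matrix(dC[i, ] / length(rows), length(rows), ncol(E),
                          byrow = TRUE)
  }
  dE <- rbind(dEs, dEq)
  nl <- length(encoder$layers)
  grads <- vector("list", nl)
  dH <- dE
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl) dH * (fc$Z[[l]] > 0) else dH
    grads[[l]] <- list(W = crossprod(fc$H[[l]], dZ), b = colSums(dZ))
    if (l > 1L) dH <- dZ %*% t(encoder$layers[[l]]$W)
  }
  list(loss = loss, grads = grads)
}

#' Train a prototypical-network encoder on source tasks
#'
#' Episodic training: at each step one source task is sampled, a
#' support/query episode is drawn from it, and the encoder is updated by Adam
#' on the cross-entropy of [classify_query()] probabilities. Deterministic
#' under `seed` (single-threaded).
#'
#' @param source_tasks List of at least 2 [bioactivity_task()]s or
#'   [embedded_dataset()]s.
#' @param featurizer Featurizer for tasks.
#' @param encoder_cfg An [encoder_config()].
#' @param seed Integer seed.
#' @return A `protonet_encoder` with frozen parameters; the per-step loss
#'   trace is in `attr(, "loss_trace")`.
#' @export
train_protonet <- function(source_tasks, featurizer = "loaded",
                           encoder_cfg = encoder_config(), seed = 1L) {
  if (length(source_tasks) < 2L)
    stop("episodic training needs at least 2 source tasks")
  dss <- lapply(source_tasks, function(t)
    if (inherits(t, "embedded_dataset")) t
    else featurize_molecules(t, featurizer))
  usable <- vapply(dss, function(d)
    length(unique(d$labels)) == 2L &&
      nrow(d$features) >= encoder_cfg$support_size + 4L, logical(1))
  if (sum(usable) < 2L) stop("fewer than 2 source tasks can form episodes")
  dss <- dss[usable]
  in_dim <- ncol(dss[[1]]$features)
  set.seed(seed)
  enc <- .init_encoder(in_dim, encoder_cfg)
  if (enc$identity || encoder_cfg$steps == 0L) {
    attr(enc, "loss_trace") <- numeric(0)
    return(enc)
  }
  # Adam state
  m <- v <- lapply(enc$layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(encoder_cfg$steps)
  for (step in seq_len(encoder_cfg$steps)) {
    ds <- dss[[sample.int(length(dss), 1L)]]
    ep <- build_episode(ds, support_size = encoder_cfg$support_size,
                        seed = seed + step)
    qn <- min(encoder_cfg$query_size, nrow(ep$query_features))
    qi <- sample.int(nrow(ep$query_features), qn)
    if (length(unique(ep$query_labels[qi])) < 2L)
      qi <- seq_len(nrow(ep$query_features))
    g <- .episode_grad(enc, ep$support_features, ep$support_labels,
                       ep$query_features[qi, , drop = FALSE],
                       ep$query_labels[qi])
    if (!is.finite(g$loss))
      stop("non-finite episode loss at step ", step)
    trace[step] <- g$loss
    for (l in seq_along(enc$layers)) {
      for (nm in c("W", "b")) {
        m[[l]][[nm]] <- b1 * m[[l]][[nm]] + (1 - b1) * g$grads[[l]][[nm]]
        v[[l]][[nm]] <- b2 * v[[l]][[nm]] + (1 - b2) * g$grads[[l]][[nm]]^2
        mhat <- m[[l]][[nm]] / (1 - b1^step)
        vhat <- v[[l]][[nm]] / (1 - b2^step)
        enc$layers[[l]][[nm]] <- enc$layers[[l]][[nm]] -
          encoder_cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  attr(enc, "loss_trace") <- trace
  enc
}

# average precision (area under the precision-recall curve, step
# interpolation): mean of precision at each positive, in rank order
.auprc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  if (sum(y == 1) == 0L) return(NA_real_)
  mean(prec[y == 1])
}

#' Evaluate a method on one task in the few-shot setting
#'
#' Draws `n_seeds` support/query episodes from the task and reports the mean
#' ROC-AUC and AUPRC on the query set. Methods: `"protonet"` (requires a
#' trained encoder), `"rf"` and `"knn"` (single-task baselines fit on the
#' support set only). Episodes whose query set degenerates to one class are
#' skipped with a message.
#'
#' @param method `"protonet"`, `"rf"` or `"knn"`.
#' @param task A [bioactivity_task()] or [embedded_dataset()].
#' @param featurizer Featurizer for tasks.
#' @param support_size Episode support size (the usual few-shot settings
#'   are 16, 32, 64 and 128).
#' @param encoder `protonet_encoder`, required for `method = "protonet"`.
#' @param n_seeds Number of episode draws averaged (default 5).
#' @param seed Base seed.
#' @param cfg A [hardness_config()] supplying rf/knn hyperparameters.
#' @return Object of class `eval_record`: list with `task_id`, `method`,
#'   `support_size`, `roc_auc`, `auprc`, `n_episodes`, `seed`.
#' @export
evaluate_task <- function(method = c("protonet", "rf", "knn"), task,
                          featurizer = "loaded", support_size = 16L,
                          encoder = NULL, n_seeds = 5L, seed = 1L,
                          cfg = hardness_config()) {
  method <- match.arg(method)
  if (method == "protonet" && is.null(encoder))
    stop("method 'protonet' requires a trained encoder")
  ds <- if (inherits(task, "embedded_dataset")) task
  else featurize_molecules(task, featurizer)
  aucs <- prcs <- numeric(0)
  for (s in seq_len(n_seeds)) {
    ep <- tryCatch(build_episode(ds, support_size = support_size,
                                 seed = seed + 1000L * s),
                   error = function(e) NULL)
    if (is.null(ep)) next
    if (length(unique(ep$query_labels)) < 2L) {
      message("task '", ds$task_id, "': degenerate query at seed ", s,
              "; skipped")
      next
    }
    scores <- if (method == "protonet") {
      Es <- encode(encoder, ep$support_features)
      Eq <- encode(encoder, ep$query_features)
      classify_query(Eq, compute_prototypes(Es, ep$support_labels))[, "1"]
    } else {
      .fit_score(method, ep$support_features, ep$support_labels,
                 ep$query_features, cfg)
    }
    aucs <- c(aucs, .roc_auc(ep$query_labels, scores))
    prcs <- c(prcs, .auprc(ep$query_labels, scores))
  }
  if (!length(aucs))
    stop("no usable episode for task '", ds$task_id, "'")
  structure(list(task_id = ds$task_id, method = method,
                 support_size = as.integer(support_size),
                 roc_auc = mean(aucs), auprc = mean(prcs, na.rm = TRUE),
                 n_episodes = length(aucs), seed = as.integer(seed)),
            class = "eval_record")
}

#' Correlation between task hardness and meta-learning gain
#'
#' The validation logic of the hardness metric: harder tasks should benefit
#' less from the meta-learner. Computes Pearson and Spearman correlations
#' between combined hardness and the gain of the meta-learner over the
#' single-task baseline (and the absolute meta-learner metric), returning the
#' per-task scatter data.
#'
#' @param report A `hardness_report`.
#' @param meta_records,baseline_records Lists of `eval_record`s for the
#'   meta-learner and the baseline on the same targets.
#' @param metric `"auprc"` (default) or `"roc_auc"`.
#' @return List with `pearson`, `spearman`, `pearson_absolute`, `n`, and a
#'   `data` data.frame (task_id, hardness, meta, baseline, gain).
#' @export
hardness_gain_correlation <- function(report, meta_records,
                                      baseline_records,
                                      metric = c("auprc", "roc_auc")) {
  metric <- match.arg(metric)
  as_df <- function(recs) data.frame(
    task_id = vapply(recs, `[[`, character(1), "task_id"),
    value = vapply(recs, `[[`, numeric(1), metric),
    stringsAsFactors = FALSE)
  mdf <- as_df(meta_records); bdf <- as_df(baseline_records)
  df <- merge(merge(data.frame(task_id = report$task_id,
                               hardness = report$combined),
                    mdf, by = "task_id"),
              bdf, by = "task_id", suffixes = c("_meta", "_base"))
  names(df)[names(df) == "value_meta"] <- "meta"
  names(df)[names(df) == "value_base"] <- "baseline"
  df$gain <- df$meta - df$baseline
  if (nrow(df) < 3L)
    stop("need >= 3 targets with both hardness and gain")
  if (sd(df$hardness) == 0 || sd(df$gain) == 0)
    stop("zero variance in hardness or gain")
  list(pearson = cor(df$hardness, df$gain),
       spearman = cor(df$hardness, df$gain, method = "spearman"),
       pearson_absolute = cor(df$hardness, df$meta),
       n = nrow(df), metric = metric, data = df)
}
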