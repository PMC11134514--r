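#' Hardness configuration
#'
#' @param k Number of nearest source tasks aggregated into each external
#'   hardness component (default 10).
#' @param ext_chem_weighting `"weighted"` (difficulty-weighted mean over the
#'   k-neighborhood, the default) or `"plain"` (arithmetic mean). Protein
#'   hardness always uses the plain mean.
#' @param weights Length-3 non-negative vector `(w_chem, w_prot, w_int)`
#'   combining the normalized components; equal weights by default. A zero
#'   weight skips that component entirely (e.g. set `w_int = 0` when no
#'   train/validation split of the target is meaningful).
#' @param int_model Single-task model for internal hardness: `"rf"` (random
#'   forest, default) or `"knn"`.
#' @param m_train Training-set size for internal hardness: 16 (default), 32
#'   or 64.
#' @param split Train/validation split strategy: `"stratified"` (default),
#'   `"random"`, or `"scaffold"` (requires scaffold keys).
#' @param rf_ntree,knn_k Model hyperparameters.
#' @param seed Base seed for splits.
#' @return List of class `hardness_config`.
#' @export
hardness_config <- function(k = 10L,
                            ext_chem_weighting = c("weighted", "plain"),
                            weights = c(1, 1, 1),
                            int_model = c("rf", "knn"),
                            m_train = 16L,
                            split = c("stratified", "random", "scaffold"),
                            rf_ntree = 500L, knn_k = 5L, seed = 1L) {
  ext_chem_weighting <- match.arg(ext_chem_weighting)
  int_model <- match.arg(int_model)
  split <- match.arg(split)
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 3L, all(weights >= 0), any(weights > 0),
            k >= 1L, m_train %in% c(16L, 32L, 64L))
  structure(list(k = as.integer(k), ext_chem_weighting = ext_chem_weighting,
                 weights = weights, int_model = int_model,
                 m_train = as.integer(m_train), split = split,
                 rf_ntree = as.integer(rf_ntree), knn_k = as.integer(knn_k),
                 seed = as.integer(seed)),
            class = "hardness_config")
}

# ROC-AUC with fixed orientation (higher score = more likely active)
.roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("0", "1"),
    direction = "<", quiet = TRUE)))
}

# train/validation split of one task; redraws if a side misses a class
.split_task <- function(labels, m_train, split, seed, scaffolds = NULL) {
  n <- length(labels)
  if (n < m_train + 2L)
    stop("task too small: ", n, " molecules for m_train = ", m_train)
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    if (split == "stratified") {
      idx <- integer(0)
      for (lab in unique(labels)) {
        rows <- which(labels == lab)
        take <- max(1L, round(m_train * length(rows) / n))
        idx <- c(idx, sample(rows, min(take, length(rows))))
      }
      # trim or top up to exactly m_train
      if (length(idx) > m_train) idx <- sample(idx, m_train)
      else if (length(idx) < m_train)
        idx <- c(idx, sample(setdiff(seq_len(n), idx),
                             m_train - length(idx)))
    } else if (split == "random") {
      idx <- sample(n, m_train)
    } else {  # scaffold: fill training from largest scaffolds first
      if (is.null(scaffolds) || length(scaffolds) != n)
        stop("scaffold split requires one scaffold key per molecule")
      sizes <- sort(table(scaffolds), decreasing = TRUE)
      idx <- integer(0)
      for (sc in names(sizes)) {
        idx <- c(idx, which(scaffolds == sc))
        if (length(idx) >= m_train) break
      }
      idx <- idx[seq_len(m_train)]
    }
    train <- sort(idx); valid <- setdiff(seq_len(n), train)
    if (length(unique(labels[train])) == 2L &&
        length(unique(labels[valid])) == 2L)
      return(list(train = train, valid = valid))
    if (split == "scaffold") break  # deterministic: redrawing cannot help
  }
  stop("could not produce a split with both classes on both sides")
}

.fit_score <- function(model, Xtr, ytr, Xva, cfg) {
  if (model == "rf") {
    wt <- 1 / table(factor(ytr, levels = c(0, 1)))
    fit <- randomForest::randomForest(
      x = Xtr, y = factor(ytr, levels = c(0, 1)),
      ntree = cfg$rf_ntree, classwt = as.numeric(wt / sum(wt)))
    predict(fit, Xva, type = "prob")[, "1"]
  } else {
    pr <- class::knn(Xtr, Xva, cl = factor(ytr, levels = c(0, 1)),
                     k = min(cfg$knn_k, nrow(Xtr)), prob = TRUE)
    p <- attr(pr, "prob")
    ifelse(pr == "1", p, 1 - p)
  }
}

#' Internal chemical-space hardness of a task
#'
#' One minus the validation ROC-AUC of a single-task classifier trained on
#' only `m_train` molecules of the task itself. A task whose actives and
#' inactives are easy to tell apart from few samples scores near 0; a task at
#' chance level scores near 0.5.
#'
#' @param task A [bioactivity_task()] or [embedded_dataset()].
#' @param featurizer Featurizer name (used when a task is passed).
#' @param cfg A [hardness_config()].
#' @param scaffolds Optional scaffold keys (one per molecule) for
#'   `split = "scaffold"`.
#' @param seed Overrides `cfg$seed` when given.
#' @return Scalar in \[0, 1\].
#' @export
internal_hardness <- function(task, featurizer = "loaded",
                              cfg = hardness_config(), scaffolds = NULL,
                              seed = NULL) {
  ds <- if (inherits(task, "embedded_dataset")) task
  else featurize_molecules(task, featurizer)
  if (length(unique(ds$labels)) < 2L)
    stop("task '", ds$task_id, "' has a single class; internal hardness ",
         "needs both actives and inactives")
  sp <- .split_task(ds$labels, cfg$m_train, cfg$split,
                    seed %||% cfg$seed, scaffolds)
  scores <- .fit_score(cfg$int_model,
                       ds$features[sp$train, , drop = FALSE],
                       ds$labels[sp$train],
                       ds$features[sp$valid, , drop = FALSE], cfg)
  1 - .roc_auc(ds$labels[sp$valid], scores)
}

#' Source-task difficulty weights
#'
#' The difficulty of each source task for a few-sample single-task learner:
#' one minus the ROC-AUC of a random forest trained on 16 of its molecules.
#' Used to weight the k-nearest-neighbor average behind external
#' chemical-space hardness, so that nearby but internally hard sources pull
#' hardness up. Sources whose hardness cannot be computed (too small,
#' single-class) receive the mean weight of the successful ones.
#'
#' @param sources List of [bioactivity_task()]s or [embedded_dataset()]s.
#' @param featurizer Featurizer for tasks.
#' @param cfg A [hardness_config()]; the model is forced to random forest
#'   with `m_train = 16` as the difficulty probe.
#' @return Named numeric vector, one weight per source task id.
#' @export
source_difficulty_weights <- function(sources, featurizer = "loaded",
                                      cfg = hardness_config()) {
  probe <- hardness_config(k = cfg$k, weights = cfg$weights,
                           int_model = "rf", m_train = 16L,
                           split = cfg$split, rf_ntree = cfg$rf_ntree,
                           seed = cfg$seed)
  ids <- vapply(sources, `[[`, character(1), "task_id")
  # one shared seed: identical sources receive identical weights
  w <- vapply(seq_along(sources), function(i) {
    tryCatch(internal_hardness(sources[[i]], featurizer, probe,
                               seed = probe$seed),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(w))) stop("internal hardness failed for every source task")
  if (anyNA(w)) {
    message(sum(is.na(w)), " source task(s) fell back to the mean weight")
    w[is.na(w)] <- mean(w, na.rm = TRUE)
  }
  setNames(pmax(w, 0), ids)
}

#' k-nearest-neighbor distance aggregation
#'
#' Distills a target's column of source distances into one number: the
#' (optionally weighted) mean over its k smallest entries. Ties are broken by
#' ascending source task id, making the selection deterministic. Weights are
#' renormalized within the selected neighborhood.
#'
#' @param column Numeric vector of distances, named by source task id.
#' @param k Neighborhood size (1 <= k <= length(column)).
#' @param weights Optional non-negative weights aligned with `column` (by
#'   name when both are named).
#' @return Scalar aggregate distance.
#' @export
knn_hardness <- function(column, k, weights = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (k > length(column)) stop("k = ", k, " exceeds ", length(column),
                               " sources")
  ids <- names(column) %||% as.character(seq_along(column))
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("negative weights")
    if (!is.null(names(weights)) && !is.null(names(column)))
      weights <- weights[names(column)]
    if (length(weights) != length(column))
      stop("weights not aligned to sources")
  }
  ord <- order(column, ids)[seq_len(k)]
  if (is.null(weights)) return(mean(column[ord]))
  w <- weights[ord]
  if (sum(w) == 0) return(mean(column[ord]))  # all-zero: fall back to plain
  sum(w * column[ord]) / sum(w)
}

#' Min-max normalization across target tasks
#'
#' Rescales a hardness component to \[0, 1\] over the target-task collection
#' of one run. A constant vector maps to all zeros.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 1L) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite input")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)) |>
                                 setNames(names(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Combined task-hardness report
#'
#' Computes the three hardness components for every target task and combines
#' them: external chemical-space hardness (k-NN aggregate of the OTDD column,
#' difficulty-weighted by default), external protein-space hardness (plain
#' k-NN aggregate of the protein distance column), and internal hardness
#' (few-sample single-task error on the target itself). Each component is
#' min-max normalized across the targets of this run, then combined as
#' `w_chem * EXT_CHEM + w_prot * EXT_PROT + w_int * INT_CHEM`. Components
#' with zero weight are skipped (reported as `NA`).
#'
#' @param chem_dm,prot_dm [distance_matrix()]s covering all targets (only
#'   required for components with nonzero weight).
#' @param targets List of target [bioactivity_task()]s or
#'   [embedded_dataset()]s (needed when `w_int > 0`).
#' @param sources List of source tasks/datasets (needed for difficulty
#'   weighting of the chemical component).
#' @param cfg A [hardness_config()].
#' @param featurizer Featurizer for tasks.
#' @return Object of class `hardness_report`: a data.frame (one row per
#'   target; raw, normalized and combined columns) with the configuration
#'   snapshot in `attr(, "provenance")`.
#' @export
compute_hardness <- function(chem_dm = NULL, prot_dm = NULL,
                             targets = NULL, sources = NULL,
                             cfg = hardness_config(),
                             featurizer = "loaded") {
  w <- cfg$weights
  tids <- if (!is.null(targets))
    vapply(targets, `[[`, character(1), "task_id")
  for (dm in list(chem_dm, prot_dm))
    if (!is.null(dm)) tids <- tids %||% dm$target_ids
  if (is.null(tids)) stop("no targets to score")

  get_col <- function(dm, tid, what) {
    if (!tid %in% dm$target_ids)
      stop("target '", tid, "' absent from the ", what, " distance matrix")
    setNames(dm$values[, tid], dm$source_ids)
  }

  ext_chem <- ext_prot <- int_chem <- rep(NA_real_, length(tids))
  if (w[1] > 0) {
    if (is.null(chem_dm)) stop("w_chem > 0 but no chemical distance matrix")
    cw <- NULL
    if (cfg$ext_chem_weighting == "weighted") {
      if (is.null(sources))
        stop("weighted EXT_CHEM requires the source tasks")
      cw <- source_difficulty_weights(sources, featurizer, cfg)
      cw <- cw[chem_dm$source_ids]
    }
    ext_chem <- vapply(tids, function(tid)
      knn_hardness(get_col(chem_dm, tid, "chemical"),
                   min(cfg$k, length(chem_dm$source_ids)), cw),
      numeric(1))
  }
  if (w[2] > 0) {
    if (is.null(prot_dm)) stop("w_prot > 0 but no protein distance matrix")
    ext_prot <- vapply(tids, function(tid)
      knn_hardness(get_col(prot_dm, tid, "protein"),
                   min(cfg$k, length(prot_dm$source_ids))),
      numeric(1))
  }
  if (w[3] > 0) {
    if (is.null(targets)) stop("w_int > 0 but no target tasks provided")
    ord <- match(tids, vapply(targets, `[[`, character(1), "task_id"))
    if (anyNA(ord)) stop("targets missing for: ",
                         paste(tids[is.na(ord)], collapse = ", "))
    int_chem <- vapply(seq_along(tids), function(i)
      internal_hardness(targets[[ord[i]]], featurizer, cfg,
                        seed = cfg$seed + i),
      numeric(1))
  }

  norm0 <- function(x, used) if (used) minmax_normalize(x)
  else rep(NA_real_, length(x))
  ecn <- norm0(ext_chem, w[1] > 0)
  epn <- norm0(ext_prot, w[2] > 0)
  icn <- norm0(int_chem, w[3] > 0)
  combined <- w[1] * ifelse(is.na(ecn), 0, ecn) +
    w[2] * ifelse(is.na(epn), 0, epn) +
    w[3] * ifelse(is.na(icn), 0, icn)

  rep_df <- data.frame(task_id = tids,
                       ext_chem_raw = unname(ext_chem),
                       ext_prot_raw = unname(ext_prot),
                       int_chem_raw = unname(int_chem),
                       ext_chem_norm = unname(ecn),
                       ext_prot_norm = unname(epn),
                       int_chem_norm = unname(icn),
                       combined = unname(combined),
                       stringsAsFactors = FALSE)
  attr(rep_df, "provenance") <- unclass(cfg)
  class(rep_df) <- c("hardness_report", "data.frame")
  rep_df
}

#' Write / read a hardness report
#'
#' CSV (one row per target task) plus a JSON provenance sidecar holding the
#' configuration snapshot.
#'
#' @param report A `hardness_report`.
#' @param path CSV file path.
#' @return `write_hardness_report`: `path` invisibly; `read_hardness_report`:
#'   the report.
#' @export
write_hardness_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  prov <- attr(report, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hardness_report
#' @export
read_hardness_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta))
    attr(df, "provenance") <- jsonlite::read_json(meta,
                                                  simplifyVector = TRUE)
  class(df) <- c("hardness_report", "data.frame")
  df
}

#' Rational source-task selection for a target
#'
#' Ranks source tasks by their distance to the target (ascending) and returns
#' the `k` most relevant. Criteria: `"chem"` (chemical distance column),
#' `"prot"` (protein distance column), or `"sum_norm"` (sum of the two
#' columns after min-max normalizing each across sources). Ties break by
#' ascending source id.
#'
#' @param target_id Target task id.
#' @param chem_dm,prot_dm [distance_matrix()]s (as required by `criterion`).
#' @param k Number of sources to select.
#' @param criterion `"sum_norm"` (default), `"chem"` or `"prot"`.
#' @return Character vector of `k` source ids, most relevant first.
#' @export
select_source_tasks <- function(target_id, chem_dm = NULL, prot_dm = NULL,
                                k, criterion = c("sum_norm", "chem",
                                                 "prot")) {
  criterion <- match.arg(criterion)
  col_of <- function(dm, what) {
    if (is.null(dm)) stop("criterion '", criterion, "' needs the ", what,
                          " distance matrix")
    if (!target_id %in% dm$target_ids)
      stop("target '", target_id, "' absent from the ", what, " matrix")
    setNames(dm$values[, target_id], dm$source_ids)
  }
  score <- switch(criterion,
    chem = col_of(chem_dm, "chemical"),
    prot = col_of(prot_dm, "protein"),
    sum_norm = {
      cc <- col_of(chem_dm, "chemical"); pp <- col_of(prot_dm, "protein")
      common <- intersect(names(cc), names(pp))
      if (length(common) == 0L) stop("no sources shared between matrices")
      minmax_normalize(cc[common]) + minmax_normalize(pp[common])
    })
  if (k > length(score))
    stop("k = ", k, " exceeds ", length(score), " sources")
  names(score)[order(score, names(score))][seq_len(k)]
}
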