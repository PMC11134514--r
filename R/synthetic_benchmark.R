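#' Synthetic task-universe configuration
#'
#' Configures a desk-scale universe of bioactivity tasks with planted
#' inter-task relatedness, so that every stage of the pipeline (OTDD,
#' protein distance, hardness, prototypical-network validation) can run and
#' be checked against ground truth with no external data. Each target task
#' carries a relatedness level `rho` in \[0, 1\]: at `rho = 1` the target's
#' chemistry anchor, labeling rule and protein anchor are shared with
#' `ceiling(rho * k_related)` designated source tasks; at `rho = 0` no source
#' shares them. Targets at the same `rho` level share one anchor cluster (and
#' hence its designated sources), which keeps the default universe feasible
#' with 50 sources.
#'
#' @param n_sources,n_targets Universe size (default 50 / 20).
#' @param chem_dim Molecule feature dimension (default 16).
#' @param prot_dim Protein embedding dimension (default 32).
#' @param n_molecules Molecules per task (default 200).
#' @param label_noise Label flip probability in \[0, 0.5\] (default 0.1).
#' @param relatedness Per-target `rho`; default cycles
#'   `c(0, 0.25, 0.5, 0.75, 1)` across targets.
#' @param k_related Designated sources at `rho = 1` (default 10, matching the
#'   default k-NN neighborhood).
#' @param anchor_sd,jitter_sd,within_sd,prot_noise_sd Geometry: spread of
#'   anchors, per-target anchor jitter, within-task molecule spread, and
#'   protein perturbation.
#' @param complex_fraction Fraction of (unrelated) sources emitted as
#'   two-protein complexes (default 0.06).
#' @param seed Universe seed (default 7).
#' @return List of class `universe_config`.
#' @export
universe_config <- function(n_sources = 50L, n_targets = 20L,
                            chem_dim = 16L, prot_dim = 32L,
                            n_molecules = 200L, label_noise = 0.1,
                            relatedness = NULL, k_related = 10L,
                            anchor_sd = 3, jitter_sd = 0.3,
                            within_sd = 1, prot_noise_sd = 0.1,
                            complex_fraction = 0.06, seed = 7L) {
  stopifnot(chem_dim >= 2L, prot_dim >= 2L, n_molecules >= 10L,
            label_noise >= 0, label_noise <= 0.5)
  relatedness <- relatedness %||%
    rep(c(0, 0.25, 0.5, 0.75, 1), length.out = n_targets)
  if (length(relatedness) != n_targets ||
      any(relatedness < 0 | relatedness > 1))
    stop("relatedness must give one value in [0,1] per target")
  structure(list(n_sources = as.integer(n_sources),
                 n_targets = as.integer(n_targets),
                 chem_dim = as.integer(chem_dim),
                 prot_dim = as.integer(prot_dim),
                 n_molecules = as.integer(n_molecules),
                 label_noise = label_noise, relatedness = relatedness,
                 k_related = as.integer(k_related), anchor_sd = anchor_sd,
                 jitter_sd = jitter_sd, within_sd = within_sd,
                 prot_noise_sd = prot_noise_sd,
                 complex_fraction = complex_fraction,
                 seed = as.integer(seed)),
            class = "universe_config")
}

.unit <- function(v) v / sqrt(sum(v^2))

# molecules of one task: 3-component Gaussian mixture around the anchor,
# labels from a linear rule through the anchor with flip noise
.gen_task_data <- function(anchor, rule, cfg) {
  d <- cfg$chem_dim
  centers <- matrix(rnorm(3 * d, sd = cfg$within_sd), 3, d)
  comp <- sample.int(3, cfg$n_molecules, replace = TRUE)
  X <- matrix(rep(anchor, each = cfg$n_molecules), cfg$n_molecules, d) +
    centers[comp, , drop = FALSE] +
    matrix(rnorm(cfg$n_molecules * d, sd = 0.75 * cfg$within_sd),
           cfg$n_molecules, d)
  # threshold at the median projection: tasks are near-balanced, mirroring
  # the nearly balanced assays of few-shot bioactivity benchmarks
  s <- drop((X - matrix(rep(anchor, each = cfg$n_molecules),
                        cfg$n_molecules, d)) %*% rule)
  y <- as.integer(s > stats::median(s))
  flip <- runif(cfg$n_molecules) < cfg$label_noise
  y[flip] <- 1L - y[flip]
  list(X = X, y = y)
}

.make_universe_task <- function(id, role, anchor, rule, prot_anchors, cfg) {
  dat <- .gen_task_data(anchor, rule, cfg)
  task <- bioactivity_task(
    id, sprintf("%s_M%04d", id, seq_len(cfg$n_molecules)), dat$y,
    role = role, features = dat$X)
  task$protein_vectors <- prot_anchors +
    matrix(rnorm(length(prot_anchors), sd = cfg$prot_noise_sd),
           nrow(prot_anchors), ncol(prot_anchors))
  task
}

#' Generate a synthetic task universe with planted relatedness
#'
#' See [universe_config()] for the generative model. Tasks carry precomputed
#' feature matrices (consumed through the `"loaded"` featurizer) and protein
#' embedding vectors; molecule entries are surrogate identifiers.
#'
#' @param cfg A [universe_config()].
#' @return List of class `task_universe` with `sources`, `targets` (lists of
#'   [bioactivity_task()]s), `truth` (per target: `rho`, `level`,
#'   `related_sources`) and `cfg`.
#' @export
generate_universe <- function(cfg = universe_config()) {
  stopifnot(inherits(cfg, "universe_config"))
  set.seed(cfg$seed)
  d <- cfg$chem_dim; e <- cfg$prot_dim
  levels <- sort(unique(cfg$relatedness[cfg$relatedness > 0]))
  n_rel <- setNames(as.integer(ceiling(levels * cfg$k_related)),
                    as.character(levels))
  if (sum(n_rel) > cfg$n_sources)
    stop("infeasible universe: ", sum(n_rel), " designated sources needed ",
         "but only ", cfg$n_sources, " available")

  level_info <- lapply(levels, function(rho) list(
    rho = rho,
    chem_anchor = rnorm(d, sd = cfg$anchor_sd),
    prot_anchor = rnorm(e, sd = cfg$anchor_sd),
    rule = .unit(rnorm(d))))
  names(level_info) <- as.character(levels)

  src_ids <- sprintf("SRC%03d", seq_len(cfg$n_sources))
  assignment <- rep(NA_character_, cfg$n_sources)
  nxt <- 1L
  for (lv in names(level_info)) {
    take <- n_rel[[lv]]
    assignment[nxt:(nxt + take - 1L)] <- lv
    nxt <- nxt + take
  }

  sources <- vector("list", cfg$n_sources)
  for (i in seq_len(cfg$n_sources)) {
    lv <- assignment[i]
    if (!is.na(lv)) {
      info <- level_info[[lv]]
      rho <- info$rho
      rule <- .unit(rho * info$rule + (1 - rho) * .unit(rnorm(d)))
      prot <- matrix(info$prot_anchor, 1L, e, byrow = TRUE)
      sources[[i]] <- .make_universe_task(src_ids[i], "source",
                                          info$chem_anchor, rule, prot, cfg)
    } else {
      prot <- matrix(rnorm(e, sd = cfg$anchor_sd), 1L, e)
      sources[[i]] <- .make_universe_task(src_ids[i], "source",
                                          rnorm(d, sd = cfg$anchor_sd),
                                          .unit(rnorm(d)), prot, cfg)
    }
  }
  # a few unrelated sources become two-protein complexes
  unrel <- which(is.na(assignment))
  n_cplx <- min(length(unrel),
                floor(cfg$complex_fraction * cfg$n_sources))
  if (n_cplx > 0) {
    for (i in utils::tail(unrel, n_cplx)) {
      extra <- matrix(rnorm(e, sd = cfg$anchor_sd), 1L, e) +
        rnorm(e, sd = cfg$prot_noise_sd)
      sources[[i]]$protein_vectors <-
        rbind(sources[[i]]$protein_vectors, extra)
      sources[[i]]$protein_ids <- paste0(src_ids[i], "_P", 1:2)
    }
  }

  tgt_ids <- sprintf("TGT%03d", seq_len(cfg$n_targets))
  targets <- vector("list", cfg$n_targets)
  truth <- vector("list", cfg$n_targets)
  for (j in seq_len(cfg$n_targets)) {
    rho <- cfg$relatedness[j]
    if (rho > 0) {
      lv <- as.character(rho)
      info <- level_info[[lv]]
      anchor <- info$chem_anchor + rnorm(d, sd = cfg$jitter_sd)
      prot <- matrix(info$prot_anchor, 1L, e, byrow = TRUE)
      targets[[j]] <- .make_universe_task(tgt_ids[j], "target", anchor,
                                          info$rule, prot, cfg)
      truth[[j]] <- list(rho = rho, level = lv,
                         related_sources = src_ids[which(assignment == lv)])
    } else {
      prot <- matrix(rnorm(e, sd = cfg$anchor_sd), 1L, e)
      targets[[j]] <- .make_universe_task(tgt_ids[j], "target",
                                          rnorm(d, sd = cfg$anchor_sd),
                                          .unit(rnorm(d)), prot, cfg)
      truth[[j]] <- list(rho = 0, level = NA_character_,
                         related_sources = character())
    }
  }
  names(truth) <- tgt_ids
  structure(list(sources = sources, targets = targets, truth = truth,
                 cfg = cfg),
            class = "task_universe")
}

#' @export
print.task_universe <- function(x, ...) {
  cat("<task_universe> ", length(x$sources), " sources, ",
      length(x$targets), " targets, d=", x$cfg$chem_dim, ", e=",
      x$cfg$prot_dim, ", seed=", x$cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Write a universe to task directories
#'
#' One directory per task (`molecules.csv`, `features.csv`, protein
#' embedding as `protein_vectors.csv`), plus `truth.json` with the planted
#' relatedness.
#'
#' @param universe A [generate_universe()] result.
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
write_universe <- function(universe, out) {
  dir.create(file.path(out, "sources"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "targets"), recursive = TRUE,
             showWarnings = FALSE)
  dump1 <- function(task, dir) {
    write_task(task, dir)
    utils::write.table(task$protein_vectors,
                       file.path(dir, "protein_vectors.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  for (t in universe$sources)
    dump1(t, file.path(out, "sources", t$task_id))
  for (t in universe$targets)
    dump1(t, file.path(out, "targets", t$task_id))
  jsonlite::write_json(universe$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Two-cluster synthetic classification task
#'
#' A single task of two Gaussian classes separated by `separation` along the
#' first feature axis; `separation = 0` gives an unlearnable task. Used to
#' calibrate internal hardness (a well-separated task should score near 0, a
#' label-permuted one near 0.5).
#'
#' @param n Molecules (default 200).
#' @param d Feature dimension (default 16).
#' @param separation Distance between class means (default 8).
#' @param seed Seed.
#' @param task_id Identifier.
#' @return A [bioactivity_task()] with attached features.
#' @export
synthetic_classification_task <- function(n = 200L, d = 16L, separation = 8,
                                          seed = 1L, task_id = "SEP") {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + ifelse(y == 1L, separation / 2, -separation / 2)
  bioactivity_task(task_id, sprintf("%s_M%04d", task_id, seq_len(n)), y,
                   features = X)
}

#' Permute the labels of a task
#'
#' Destroys the feature-label association while keeping the label balance;
#' the null case for internal-hardness calibration.
#'
#' @param task A [bioactivity_task()].
#' @param seed Seed for the permutation.
#' @return The task with permuted labels.
#' @export
permute_labels <- function(task, seed = 1L) {
  set.seed(seed)
  task$labels <- sample(task$labels)
  task
}

#' Parameter-recovery report for a synthetic universe
#'
#' Checks that the hardness components recover the planted relatedness and
#' that combined hardness anti-correlates with the meta-learning gain:
#' Pearson/Spearman correlations of planted `rho` with each component, the
#' hardness-gain correlation, and a shuffled-`rho` negative control.
#'
#' @param universe A [generate_universe()] result.
#' @param report The `hardness_report` computed on the universe.
#' @param meta_records,baseline_records Optional `eval_record` lists for the
#'   gain correlation.
#' @param thresholds Pass thresholds: `ext_chem` (corr(rho, EXT_CHEM) must be
#'   at most this), `gain` (corr(hardness, gain) at most this), `control`
#'   (|shuffled-rho corr| at most this).
#' @param control_seed Seed of the shuffled-`rho` control.
#' @return List with the correlations, the control, pass flags and the
#'   merged per-target data.
#' @export
recovery_report <- function(universe, report, meta_records = NULL,
                            baseline_records = NULL,
                            thresholds = list(ext_chem = -0.7, gain = -0.5,
                                              control = 0.3),
                            control_seed = 1L) {
  rho <- vapply(universe$truth, `[[`, numeric(1), "rho")
  df <- merge(data.frame(task_id = names(rho), rho = unname(rho)),
              as.data.frame(report), by = "task_id")
  corr_of <- function(col) {
    v <- df[[col]]
    if (all(is.na(v)) || sd(v, na.rm = TRUE) == 0) return(NA_real_)
    cor(df$rho, v, use = "complete.obs")
  }
  out <- list(
    corr_rho_ext_chem = corr_of("ext_chem_raw"),
    corr_rho_ext_prot = corr_of("ext_prot_raw"),
    corr_rho_int_chem = corr_of("int_chem_raw"),
    corr_rho_combined = corr_of("combined"),
    spearman_rho_ext_chem = if (sd(df$ext_chem_raw, na.rm = TRUE) > 0)
      cor(df$rho, df$ext_chem_raw, method = "spearman",
          use = "complete.obs") else NA_real_)
  set.seed(control_seed)
  rho_shuf <- sample(df$rho)
  out$corr_control <- if (sd(df$ext_chem_raw, na.rm = TRUE) > 0)
    cor(rho_shuf, df$ext_chem_raw, use = "complete.obs") else NA_real_
  if (!is.null(meta_records) && !is.null(baseline_records)) {
    hg <- hardness_gain_correlation(report, meta_records, baseline_records)
    out$corr_hardness_gain <- hg$pearson
    out$spearman_hardness_gain <- hg$spearman
    df <- merge(df, hg$data[, c("task_id", "meta", "baseline", "gain")],
                by = "task_id", all.x = TRUE)
  }
  out$pass <- list(
    ext_chem = is.finite(out$corr_rho_ext_chem) &&
      out$corr_rho_ext_chem <= thresholds$ext_chem,
    gain = if (is.null(out$corr_hardness_gain)) NA else
      is.finite(out$corr_hardness_gain) &&
      out$corr_hardness_gain <= thresholds$gain,
    control = is.finite(out$corr_control) &&
      abs(out$corr_control) <= thresholds$control)
  out$data <- df
  out
}
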