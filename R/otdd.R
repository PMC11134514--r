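#' OTDD configuration
#'
#' Settings for the optimal transport dataset distance between two labeled
#' molecule sets. The order is fixed at p = 2: the label-to-label cost uses
#' the closed-form 2-Wasserstein distance between Gaussian label models, the
#' ground cost is squared, and the reported distance is the square root of
#' the optimal transport cost.
#'
#' @param solver `"auto"` (exact when the cost matrix has at most
#'   `exact_max_entries` entries, Sinkhorn otherwise), `"exact"` or
#'   `"sinkhorn"`.
#' @param sinkhorn_epsilon Entropic regularization strength; `NULL` means
#'   `0.1 * mean(cost)` chosen per pair.
#' @param max_samples_per_task Subsampling cap per dataset (stratified by
#'   label, seeded).
#' @param covariance_shrinkage Relative shrinkage toward
#'   `(trace/d) * I` applied to each class covariance.
#' @param covariance_floor Absolute diagonal floor added to each class
#'   covariance; guards classes with fewer samples than dimensions.
#' @param exact_max_entries Cost-matrix size limit for the exact solver under
#'   `solver = "auto"`.
#' @param sinkhorn_max_iter,sinkhorn_tol Sinkhorn iteration cap and marginal
#'   tolerance.
#' @param seed Seed for the stratified subsample.
#' @return List of class `otdd_config`.
#' @export
otdd_config <- function(solver = c("auto", "exact", "sinkhorn"),
                        sinkhorn_epsilon = NULL,
                        max_samples_per_task = 1000L,
                        covariance_shrinkage = 1e-3,
                        covariance_floor = 1e-8,
                        exact_max_entries = 250000L,
                        sinkhorn_max_iter = 20000L,
                        sinkhorn_tol = 1e-9,
                        seed = 1L) {
  solver <- match.arg(solver)
  if (!is.null(sinkhorn_epsilon) && sinkhorn_epsilon <= 0)
    stop("sinkhorn_epsilon must be > 0")
  stopifnot(max_samples_per_task >= 1, covariance_shrinkage >= 0,
            covariance_floor >= 0)
  structure(list(p = 2, solver = solver, sinkhorn_epsilon = sinkhorn_epsilon,
                 max_samples_per_task = as.integer(max_samples_per_task),
                 covariance_shrinkage = covariance_shrinkage,
                 covariance_floor = covariance_floor,
                 exact_max_entries = as.integer(exact_max_entries),
                 sinkhorn_max_iter = as.integer(sinkhorn_max_iter),
                 sinkhorn_tol = sinkhorn_tol,
                 seed = as.integer(seed)),
            class = "otdd_config")
}

#' Fit per-class Gaussian label models
#'
#' OTDD replaces the label of each sample by the distribution of features
#' carrying that label; modeling that distribution as a Gaussian gives the
#' label-to-label cost a closed form. The covariance uses denominator n (not
#' n - 1) so single-sample classes are well-defined, then is shrunk toward
#' `(trace/d) * I` and floored on the diagonal.
#'
#' @param ds An [embedded_dataset()].
#' @param shrinkage Relative shrinkage coefficient (>= 0).
#' @param floor Absolute diagonal floor (>= 0).
#' @return Named list (one element per label present, names `"0"`/`"1"`) of
#'   `gaussian_label_model` objects with fields `label`, `mean`,
#'   `covariance`, `n_samples`.
#' @export
fit_label_gaussians <- function(ds, shrinkage = 0, floor = 0) {
  stopifnot(inherits(ds, "embedded_dataset"))
  d <- ncol(ds$features)
  if (d == 0L) stop("zero-dimensional features")
  out <- list()
  for (lab in sort(unique(ds$labels))) {
    X <- ds$features[ds$labels == lab, , drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    S <- crossprod(Xc) / nrow(X)
    S <- (S + t(S)) / 2
    S <- S + (shrinkage * sum(diag(S)) / d + floor) * diag(d)
    out[[as.character(lab)]] <-
      structure(list(label = lab, mean = mu, covariance = S,
                     n_samples = nrow(X)),
                class = "gaussian_label_model")
  }
  out
}

# symmetric PSD square root via eigendecomposition, negatives clipped
.sqrtm_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Closed-form 2-Wasserstein distance between two Gaussians
#'
#' The Bures formula:
#' `W2^2 = ||mu1 - mu2||^2 + tr(S1 + S2 - 2 (S2^{1/2} S1 S2^{1/2})^{1/2})`.
#' Matrix square roots use symmetric eigendecomposition with negative
#' eigenvalues clipped to 0; the trace term is clipped at 0 before the final
#' square root.
#'
#' @param g1,g2 `gaussian_label_model` objects of equal dimension.
#' @return Non-negative scalar.
#' @export
wasserstein2_gaussians <- function(g1, g2) {
  if (length(g1$mean) != length(g2$mean))
    stop("dimension mismatch: ", length(g1$mean), " vs ", length(g2$mean))
  if (any(!is.finite(g1$mean)) || any(!is.finite(g2$mean)) ||
      any(!is.finite(g1$covariance)) || any(!is.finite(g2$covariance)))
    stop("non-finite Gaussian parameters")
  dmu2 <- sum((g1$mean - g2$mean)^2)
  s2h <- .sqrtm_psd(g2$covariance)
  cross <- .sqrtm_psd(s2h %*% g1$covariance %*% s2h)
  tr1 <- sum(diag(g1$covariance)); tr2 <- sum(diag(g2$covariance))
  tr <- tr1 + tr2 - 2 * sum(diag(cross))
  # clip at 0 and drop eigendecomposition dust so W2(g, g) is exactly 0
  tr <- max(tr, 0)
  if (tr < 1e-12 * (tr1 + tr2)) tr <- 0
  sqrt(dmu2 + tr)
}

#' Feature-label ground cost matrix
#'
#' Entry (i, j) is the squared ground cost between sample i of `dsA` and
#' sample j of `dsB`: squared Euclidean feature distance plus the squared
#' 2-Wasserstein distance between the Gaussian models of their labels.
#'
#' @param dsA,dsB [embedded_dataset()]s.
#' @param labelsW Matrix of label-to-label W2 distances with rownames = labels
#'   of `dsA` present, colnames = labels of `dsB` present (as built by
#'   [label_w2_table()]).
#' @return Numeric matrix (nA x nB).
#' @export
ground_cost_matrix <- function(dsA, dsB, labelsW) {
  la <- as.character(dsA$labels); lb <- as.character(dsB$labels)
  if (!all(unique(la) %in% rownames(labelsW)) ||
      !all(unique(lb) %in% colnames(labelsW)))
    stop("labelsW is missing a label pair present in the data")
  D <- .cpp_sqeuclidean(dsA$features, dsB$features)
  out <- D + labelsW[la, lb, drop = FALSE]^2
  dimnames(out) <- NULL
  out
}

#' Label-to-label 2-Wasserstein table between two datasets
#'
#' @param gA,gB Outputs of [fit_label_gaussians()] for the two datasets.
#' @return Matrix of W2 distances, rows = labels of A, cols = labels of B.
#' @export
label_w2_table <- function(gA, gB) {
  W <- matrix(0, length(gA), length(gB), dimnames = list(names(gA), names(gB)))
  for (i in names(gA)) for (j in names(gB))
    W[i, j] <- wasserstein2_gaussians(gA[[i]], gB[[j]])
  W
}

#' Exact discrete optimal transport
#'
#' Solves the transportation linear program by a transportation simplex
#' (northwest-corner start, u-v pricing), returning the optimal coupling and
#' its cost.
#'
#' @param cost Finite cost matrix (n x m).
#' @param a,b Probability vectors over rows / columns (default uniform).
#' @return Object of class `transport_plan`: `plan`, `cost`, `a`, `b`,
#'   `solver`, `converged`.
#' @export
solve_exact_ot <- function(cost, a = NULL, b = NULL) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("non-finite cost matrix")
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  .check_marginals(a, b, n, m)
  res <- .cpp_transport_simplex(cost, a, b,
                                max_iter = max(200000L, 50L * (n + m)))
  if (!res$converged)
    warning("exact OT solver hit its iteration cap; solution may be suboptimal")
  structure(list(plan = res$plan, cost = res$cost, a = a, b = b,
                 solver = "exact", converged = res$converged),
            class = "transport_plan")
}

.check_marginals <- function(a, b, n, m) {
  if (length(a) != n || length(b) != m)
    stop("marginal length mismatch")
  if (any(a < 0) || any(b < 0))
    stop("negative marginals")
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8)
    stop("marginals must each sum to 1 (within 1e-8)")
}

#' Entropic-regularized optimal transport (Sinkhorn)
#'
#' Log-domain Sinkhorn iterations; the reported cost is `<plan, cost>`
#' without the entropy term, so it upper-bounds the exact optimum and
#' approaches it as `epsilon` decreases.
#'
#' @param cost Finite cost matrix.
#' @param a,b Probability vectors (default uniform).
#' @param epsilon Regularization strength (> 0).
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the worst marginal violation.
#' @return A `transport_plan` with `solver = "sinkhorn"`; `converged` is
#'   `FALSE` (with a warning) if `max_iter` is reached first.
#' @export
solve_sinkhorn <- function(cost, a = NULL, b = NULL, epsilon,
                           max_iter = 20000L, tol = 1e-9) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("non-finite cost matrix")
  if (epsilon <= 0) stop("epsilon must be > 0")
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  .check_marginals(a, b, n, m)
  res <- .cpp_sinkhorn_log(cost, a, b, epsilon, as.integer(max_iter), tol)
  P <- res$plan
  converged <- res$converged
  if (!converged)
    warning("Sinkhorn did not reach tol ", tol, " within ", max_iter,
            " iterations (marginal violation ",
            format(max(abs(rowSums(P) - a)), digits = 3), ")")
  # round onto the transport polytope: the returned plan is exactly
  # feasible, so its cost upper-bounds the exact optimum
  P <- P * pmin(1, a / pmax(rowSums(P), .Machine$double.xmin))
  P <- t(t(P) * pmin(1, b / pmax(colSums(P), .Machine$double.xmin)))
  ea <- a - rowSums(P); eb <- b - colSums(P)
  if (sum(abs(ea)) > 0) P <- P + outer(ea, eb) / sum(abs(ea))
  structure(list(plan = P, cost = sum(P * cost), a = a, b = b,
                 solver = "sinkhorn", epsilon = epsilon,
                 converged = converged),
            class = "transport_plan")
}

# stratified subsample of an embedded dataset to at most cap rows
.subsample_stratified <- function(ds, cap, seed) {
  n <- nrow(ds$features)
  if (n <= cap) return(ds)
  set.seed(seed)
  idx <- integer(0)
  for (lab in sort(unique(ds$labels))) {
    rows <- which(ds$labels == lab)
    take <- max(1L, round(cap * length(rows) / n))
    idx <- c(idx, if (length(rows) <= take) rows
             else sort(sample(rows, take)))
  }
  idx <- sort(idx)
  embedded_dataset(ds$task_id, ds$features[idx, , drop = FALSE],
                   ds$labels[idx], ds$featurizer_name, ds$standardized)
}

#' Optimal transport dataset distance between two labeled molecule sets
#'
#' The engine behind external chemical-space hardness: each dataset is
#' (optionally) subsampled with label stratification, per-class Gaussian
#' label models are fitted, the squared feature-label ground cost is built,
#' the transport problem is solved with uniform marginals, and the distance
#' is the square root of the optimal cost.
#'
#' @param dsA,dsB [embedded_dataset()]s under the same featurizer.
#' @param cfg An [otdd_config()].
#' @return Non-negative scalar distance.
#' @export
otdd_distance <- function(dsA, dsB, cfg = otdd_config()) {
  stopifnot(inherits(dsA, "embedded_dataset"),
            inherits(dsB, "embedded_dataset"))
  if (!identical(dsA$featurizer_name, dsB$featurizer_name))
    stop("featurizer mismatch: ", dsA$featurizer_name, " vs ",
         dsB$featurizer_name)
  dsA <- .subsample_stratified(dsA, cfg$max_samples_per_task, cfg$seed)
  dsB <- .subsample_stratified(dsB, cfg$max_samples_per_task, cfg$seed + 1L)
  gA <- fit_label_gaussians(dsA, cfg$covariance_shrinkage,
                            cfg$covariance_floor)
  gB <- fit_label_gaussians(dsB, cfg$covariance_shrinkage,
                            cfg$covariance_floor)
  cost <- ground_cost_matrix(dsA, dsB, label_w2_table(gA, gB))
  solver <- cfg$solver
  if (solver == "auto")
    solver <- if (length(cost) <= cfg$exact_max_entries) "exact"
              else "sinkhorn"
  plan <- if (solver == "exact") solve_exact_ot(cost)
  else solve_sinkhorn(cost,
                      epsilon = cfg$sinkhorn_epsilon %||%
                        (0.1 * mean(cost)),
                      max_iter = cfg$sinkhorn_max_iter,
                      tol = cfg$sinkhorn_tol)
  sqrt(max(plan$cost, 0))
}

#' Source-by-target chemical-space distance matrix
#'
#' OTDD between every (source, target) pair of featurized tasks. Pairs that
#' fail are recorded as `NA` with a message and the affected target columns
#' are dropped before the matrix is assembled (the distance-matrix contract
#' requires finite entries). Completed pairs can be cached to a directory and
#' are not recomputed on a rerun.
#'
#' @param sources,targets Lists of [embedded_dataset()]s.
#' @param cfg An [otdd_config()].
#' @param cache_dir Optional directory for per-pair result caching.
#' @return A [distance_matrix()] with `space = "chem"`.
#' @export
chem_distance_matrix <- function(sources, targets, cfg = otdd_config(),
                                 cache_dir = NULL) {
  sid <- vapply(sources, `[[`, character(1), "task_id")
  tid <- vapply(targets, `[[`, character(1), "task_id")
  if (!is.null(cache_dir))
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  vals <- matrix(NA_real_, length(sid), length(tid),
                 dimnames = list(sid, tid))
  for (j in seq_along(targets)) {
    for (i in seq_along(sources)) {
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(sid[i], "__", tid[j], ".rdscsv"))
      if (!is.null(cache_dir) && file.exists(cache_file)) {
        vals[i, j] <- as.numeric(readLines(cache_file, n = 1L))
        next
      }
      v <- tryCatch(otdd_distance(sources[[i]], targets[[j]], cfg),
                    error = function(e) {
                      message("OTDD failed for pair (", sid[i], ", ", tid[j],
                              "): ", conditionMessage(e))
                      NA_real_
                    })
      vals[i, j] <- v
      if (!is.null(cache_dir) && is.finite(v))
        writeLines(format(v, digits = 17), cache_file)
    }
  }
  failed <- colSums(!is.finite(vals)) > 0
  if (any(failed)) {
    message("dropping target(s) with failed pairs: ",
            paste(tid[failed], collapse = ", "))
    vals <- vals[, !failed, drop = FALSE]
    tid <- tid[!failed]
  }
  distance_matrix(vals, sid, tid, space = "chem",
                  metadata = list(
                    featurizer = sources[[1]]$featurizer_name,
                    solver = cfg$solver, epsilon = cfg$sinkhorn_epsilon,
                    max_samples_per_task = cfg$max_samples_per_task,
                    covariance_shrinkage = cfg$covariance_shrinkage,
                    seed = cfg$seed,
                    standardized = sources[[1]]$standardized))
}
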