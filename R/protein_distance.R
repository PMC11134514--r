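#' Distance between two protein embedding vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @param metric `"euclidean"` (default) or `"cosine"` (1 minus cosine
#'   similarity, in \[0, 2\]; both vectors must be non-zero).
#' @return Non-negative scalar.
#' @export
protein_pair_distance <- function(u, v, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (length(u) != length(v))
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  if (metric == "euclidean") {
    sqrt(sum((u - v)^2))
  } else {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
      stop("cosine distance undefined for a zero vector")
    d <- 1 - sum(u * v) / (nu * nv)
    min(max(d, 0), 2)
  }
}

#' Protein-space distance from a target task to a source task
#'
#' Target tasks are single-protein by construction. When the source task is a
#' protein complex (multiple sequences), the distance from the target protein
#' to every complex member is computed and the largest is kept: the complex
#' is only as close as its most distant member.
#'
#' @param target `protein_embedding` with exactly one protein.
#' @param source `protein_embedding` with at least one protein.
#' @param metric Passed to [protein_pair_distance()].
#' @return Non-negative scalar.
#' @export
task_protein_distance <- function(target, source,
                                  metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(target, "protein_embedding"),
            inherits(source, "protein_embedding"))
  if (nrow(target$vectors) != 1L)
    stop("target task '", target$task_id, "' must have exactly one protein (",
         nrow(target$vectors), " found)")
  if (nrow(source$vectors) < 1L)
    stop("source task '", source$task_id, "' has no proteins")
  max(vapply(seq_len(nrow(source$vectors)), function(i)
    protein_pair_distance(target$vectors[1, ], source$vectors[i, ], metric),
    numeric(1)))
}

#' Source-by-target protein-space distance matrix
#'
#' Sources lacking protein annotation are excluded (with a message) rather
#' than failing the whole matrix; targets must all be single-protein.
#'
#' @param sources,targets Lists of `protein_embedding`s (or
#'   [bioactivity_task()]s, which are embedded with `embedder`). Sources with
#'   no proteins are skipped.
#' @param metric Passed to [protein_pair_distance()].
#' @param embedder Used only when tasks are passed.
#' @return A [distance_matrix()] with `space = "prot"`.
#' @export
prot_distance_matrix <- function(sources, targets,
                                 metric = c("euclidean", "cosine"),
                                 embedder = "onehot2mer") {
  metric <- match.arg(metric)
  as_pe <- function(x) {
    if (inherits(x, "protein_embedding")) x
    else protein_embedding(x, embedder)
  }
  has_prot <- function(x) {
    if (inherits(x, "protein_embedding")) nrow(x$vectors) >= 1L
    else length(x$proteins) >= 1L || !is.null(x$protein_vectors)
  }
  keep <- vapply(sources, has_prot, logical(1))
  if (!all(keep))
    message("excluding ", sum(!keep),
            " source task(s) without protein annotation")
  if (!any(keep)) stop("no source task has protein annotation")
  src <- lapply(sources[keep], as_pe)
  tgt <- lapply(targets, as_pe)
  emb <- unique(vapply(c(src, tgt), `[[`, character(1), "embedder_name"))
  if (length(emb) != 1L)
    stop("mixed protein embedders: ", paste(emb, collapse = ", "))
  sid <- vapply(src, `[[`, character(1), "task_id")
  tid <- vapply(tgt, `[[`, character(1), "task_id")
  vals <- matrix(0, length(src), length(tgt), dimnames = list(sid, tid))
  for (j in seq_along(tgt)) for (i in seq_along(src))
    vals[i, j] <- task_protein_distance(tgt[[j]], src[[i]], metric)
  distance_matrix(vals, sid, tid, space = "prot",
                  metadata = list(embedder = emb, metric = metric))
}
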