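#' Construct an embedded dataset
#'
#' The featurized form of one task under one featurizer: a real feature matrix
#' plus the binary label vector, the input to OTDD and to the single-task
#' classifiers.
#'
#' @param task_id Task identifier.
#' @param features Numeric matrix (n_molecules x d), finite.
#' @param labels Binary vector, length `nrow(features)`.
#' @param featurizer_name Name of the featurizer that produced `features`.
#' @param standardized Logical flag recording whether
#'   [standardize_features()] has been applied.
#' @return An object of class `embedded_dataset`.
#' @export
embedded_dataset <- function(task_id, features, labels, featurizer_name,
                             standardized = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features/labels length mismatch for task '", task_id, "'")
  if (nrow(features) == 0L) stop("empty dataset for task '", task_id, "'")
  if (ncol(features) == 0L) stop("zero-dimensional features for task '",
                                 task_id, "'")
  if (any(!is.finite(features)))
    stop("non-finite features for task '", task_id, "'")
  if (any(!labels %in% c(0L, 1L)))
    stop("labels outside {0,1} for task '", task_id, "'")
  structure(list(task_id = task_id, features = features, labels = labels,
                 featurizer_name = featurizer_name,
                 standardized = isTRUE(standardized)),
            class = "embedded_dataset")
}

#' @export
print.embedded_dataset <- function(x, ...) {
  cat("<embedded_dataset> ", x$task_id, ": ", nrow(x$features), " x ",
      ncol(x$features), " [", x$featurizer_name, "]",
      if (x$standardized) " (standardized)", "\n", sep = "")
  invisible(x)
}

# fixed descriptor layout of the local 2D featurizer: numeric obabel
# descriptors plus element/ring counts, giving a constant dimension
.desc2d_obabel <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
                    "atoms", "bonds", "sbonds", "dbonds", "tbonds", "abonds",
                    "rotors")
.desc2d_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Names of the local 2D descriptor set
#'
#' @return Character vector of descriptor names; its length is the feature
#'   dimension of the `desc2d` featurizer.
#' @export
desc2d_names <- function() {
  c(.desc2d_obabel, paste0("n", .desc2d_elements), "rings", "aromatic_rings")
}

#' Compute local 2D physico-chemical descriptors for SMILES
#'
#' A fixed-length descriptor vector per molecule: physico-chemical descriptors
#' from the Open Babel toolkit (molecular weight, logP, TPSA, molar
#' refractivity, hydrogen-bond donor/acceptor counts, atom/bond/rotor counts)
#' plus per-element atom counts and ring counts. Stands in the same role as
#' larger 2D descriptor sets used for bioactivity modeling; the feature
#' dimension equals `length(desc2d_names())`.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, `length(smiles)` rows; rows that fail descriptor
#'   computation are `NA` (callers drop and log them).
#' @export
desc2d_descriptors <- function(smiles) {
  if (Sys.which("obabel") == "")
    stop("the desc2d featurizer requires the 'obabel' executable on PATH")
  n <- length(smiles)
  out <- matrix(NA_real_, n, length(desc2d_names()),
                dimnames = list(NULL, desc2d_names()))
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file), add = TRUE)
  # title = row index so failed molecules can be mapped back
  writeLines(paste(smiles, seq_len(n)), smi_file)
  res <- suppressWarnings(system2(
    "obabel", c(smi_file, "-otxt", "--append",
                paste(.desc2d_obabel, collapse = " ")),
    stdout = TRUE, stderr = FALSE))
  for (line in res) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) != length(.desc2d_obabel) + 1L) next
    i <- suppressWarnings(as.integer(f[1]))
    if (is.na(i)) next
    out[i, seq_along(.desc2d_obabel)] <- as.numeric(f[-1])
  }
  counts <- t(vapply(smiles, .smiles_counts,
                     numeric(length(.desc2d_elements) + 2L),
                     USE.NAMES = FALSE))
  out[, (length(.desc2d_obabel) + 1L):ncol(out)] <- counts
  bad <- rowSums(is.na(out)) > 0
  out[bad, ] <- NA_real_
  out
}

# element and ring counts from the parsed molecular graph
.smiles_counts <- function(s) {
  res <- rep(NA_real_, length(.desc2d_elements) + 2L)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) return(res)
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(s)), silent = TRUE)
  if (inherits(sdf, "try-error")) return(res)
  ab <- ChemmineR::atomblock(sdf[[1]])
  elems <- gsub("_.*$", "", rownames(ab))
  res[seq_along(.desc2d_elements)] <-
    vapply(.desc2d_elements, function(e) sum(elems == e), numeric(1))
  ri <- try(suppressWarnings(
    ChemmineR::rings(sdf[[1]], type = "count", arom = TRUE)), silent = TRUE)
  if (inherits(ri, "try-error")) {
    res[length(res) - 1L] <- 0; res[length(res)] <- 0
  } else {
    res[length(res) - 1L] <- as.numeric(ri["RINGS"])
    res[length(res)] <- as.numeric(ri["AROMATIC"])
  }
  res
}

#' Featurize the molecules of a task
#'
#' Turns a task's molecules into an [embedded_dataset()]. Featurizers:
#' \describe{
#'   \item{`desc2d`}{local 2D physico-chemical descriptors
#'     ([desc2d_descriptors()]); molecules failing descriptor computation are
#'     dropped with a message, together with their labels.}
#'   \item{`loaded`}{the feature matrix attached to the task (e.g. from a
#'     pretrained molecule encoder, or from the synthetic universe
#'     generator).}
#'   \item{`loaded:<path>`}{features read from `<path>` via
#'     [load_embeddings()].}
#' }
#'
#' @param task A [bioactivity_task()].
#' @param featurizer Featurizer name (see Details).
#' @return An [embedded_dataset()].
#' @export
featurize_molecules <- function(task, featurizer = "desc2d") {
  stopifnot(inherits(task, "bioactivity_task"))
  if (length(task$molecules) == 0L)
    stop("task '", task$task_id, "' has no molecules")
  if (featurizer == "desc2d") {
    feats <- desc2d_descriptors(task$molecules)
    keep <- rowSums(is.na(feats)) == 0
    if (!any(keep))
      stop("task '", task$task_id, "': all molecules failed featurization")
    if (!all(keep))
      message("task '", task$task_id, "': dropped ", sum(!keep),
              " molecule(s) failing descriptor computation (rows ",
              paste(which(!keep), collapse = ", "), ")")
    embedded_dataset(task$task_id, feats[keep, , drop = FALSE],
                     task$labels[keep], "desc2d")
  } else if (featurizer == "loaded") {
    if (is.null(task$features))
      stop("task '", task$task_id, "' carries no precomputed features")
    embedded_dataset(task$task_id, task$features, task$labels, "loaded")
  } else if (startsWith(featurizer, "loaded:")) {
    load_embeddings(sub("^loaded:", "", featurizer), task)
  } else {
    stop("unknown featurizer '", featurizer, "'")
  }
}

#' Load precomputed molecule embeddings for a task
#'
#' Reads a per-task embedding matrix written by an external featurizer
#' (pretrained molecule encoders are treated as loadable features). Two
#' layouts are accepted: a headerless CSV with one row per molecule in task
#' order, or a CSV whose first column `smiles` keys rows by molecule string.
#'
#' @param path CSV file.
#' @param task The [bioactivity_task()] the embeddings belong to.
#' @return An [embedded_dataset()] with `featurizer_name = "loaded"`.
#' @export
load_embeddings <- function(path, task) {
  stopifnot(inherits(task, "bioactivity_task"))
  first <- readLines(path, n = 1L)
  keyed <- grepl("^\\s*\"?smiles\"?\\s*,", first)
  if (keyed) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    idx <- match(task$molecules, df$smiles)
    if (anyNA(idx))
      stop("embeddings at ", path, " missing molecule(s): ",
           paste(utils::head(task$molecules[is.na(idx)], 5), collapse = ", "))
    mat <- as.matrix(df[idx, setdiff(names(df), "smiles"), drop = FALSE])
  } else {
    mat <- as.matrix(utils::read.csv(path, header = FALSE))
    if (nrow(mat) != length(task$molecules))
      stop("embeddings at ", path, " have ", nrow(mat), " rows but task '",
           task$task_id, "' has ", length(task$molecules), " molecules")
  }
  dimnames(mat) <- NULL
  embedded_dataset(task$task_id, mat, task$labels, "loaded")
}

#' Pool-standardize feature matrices
#'
#' Centers and scales each feature dimension to zero mean and unit variance,
#' pooled over all provided datasets (OTDD's ground cost is Euclidean, so
#' descriptor scales matter). Zero-variance dimensions map to 0. The returned
#' statistics can be re-applied to held-out datasets.
#'
#' @param datasets List of [embedded_dataset()]s sharing one featurizer.
#' @param stats Optional statistics from a previous call (named list with
#'   `mean` and `sd`); when given, those are applied instead of re-estimated.
#' @return List with `datasets` (standardized) and `stats`.
#' @export
standardize_features <- function(datasets, stats = NULL) {
  stopifnot(length(datasets) >= 1L)
  fn <- unique(vapply(datasets, `[[`, character(1), "featurizer_name"))
  if (length(fn) != 1L)
    stop("mixed featurizers: ", paste(fn, collapse = ", "))
  d <- unique(vapply(datasets, function(x) ncol(x$features), integer(1)))
  if (length(d) != 1L) stop("mixed feature dimensions")
  if (is.null(stats)) {
    pooled <- do.call(rbind, lapply(datasets, `[[`, "features"))
    mu <- colMeans(pooled)
    # denominator n: idempotent under re-application of own stats
    sdv <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
    stats <- list(mean = mu, sd = sdv)
  }
  sdv <- ifelse(stats$sd > 0, stats$sd, 1)
  out <- lapply(datasets, function(x) {
    z <- sweep(sweep(x$features, 2, stats$mean), 2, sdv, "/")
    z[, stats$sd == 0] <- 0
    embedded_dataset(x$task_id, z, x$labels, x$featurizer_name,
                     standardized = TRUE)
  })
  list(datasets = out, stats = stats)
}

.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Embed a protein sequence
#'
#' Protein representations are the mean over per-residue token vectors. The
#' built-in `onehot2mer` embedder needs no model download: each residue's
#' token is its one-hot vector over the 20 standard amino acids plus X, and
#' the mean one-hot block (residue composition) is concatenated with the
#' relative 2-mer count profile of the sequence. Pretrained protein language
#' model embeddings are supplied through the loaded-embedding path of
#' [protein_embedding()] instead.
#'
#' @param sequence Non-empty amino-acid string (single-letter code, `X`
#'   allowed for unknown residues).
#' @param embedder Only `"onehot2mer"` is computed locally.
#' @return Numeric vector of length `21 + 21^2`.
#' @export
embed_protein <- function(sequence, embedder = "onehot2mer") {
  stopifnot(identical(embedder, "onehot2mer"))
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty protein sequence")
  res <- strsplit(sequence, "")[[1]]
  idx <- match(res, .aa_alphabet)
  if (anyNA(idx))
    stop("illegal residue(s) in sequence: ",
         paste(unique(res[is.na(idx)]), collapse = ", "))
  onehot <- tabulate(idx, nbins = 21L) / length(idx)
  kmer <- numeric(21L^2)
  if (length(idx) >= 2L) {
    pair <- (idx[-length(idx)] - 1L) * 21L + idx[-1L]
    kmer <- tabulate(pair, nbins = 21L^2) / (length(idx) - 1L)
  }
  c(onehot, kmer)
}

#' Protein embedding matrix for a task
#'
#' One row per protein in the task; tasks representing protein complexes get
#' multiple rows. Precomputed embeddings (e.g. from a protein language model,
#' mean-pooled over residues) are read from `embedder = "loaded:<path>"`, a
#' headerless CSV with one row per protein in FASTA order.
#'
#' @param task A [bioactivity_task()].
#' @param embedder `"onehot2mer"` or `"loaded:<path>"`.
#' @return Object of class `protein_embedding`: list with `task_id`,
#'   `vectors` (n_proteins x e) and `embedder_name`.
#' @export
protein_embedding <- function(task, embedder = "onehot2mer") {
  stopifnot(inherits(task, "bioactivity_task"))
  if (!is.null(task$protein_vectors)) {
    vec <- as.matrix(task$protein_vectors)
    if (any(!is.finite(vec)))
      stop("non-finite protein embedding for task '", task$task_id, "'")
    return(structure(list(task_id = task$task_id, vectors = vec,
                          embedder_name = "loaded"),
                     class = "protein_embedding"))
  }
  if (length(task$proteins) == 0L)
    stop("task '", task$task_id, "' has no protein sequences")
  if (startsWith(embedder, "loaded:")) {
    vec <- as.matrix(utils::read.csv(sub("^loaded:", "", embedder),
                                     header = FALSE))
    dimnames(vec) <- NULL
    if (nrow(vec) != length(task$proteins))
      stop("loaded protein embeddings: ", nrow(vec), " rows for ",
           length(task$proteins), " proteins of task '", task$task_id, "'")
    name <- "loaded"
  } else {
    vec <- t(vapply(task$proteins, embed_protein, numeric(21L + 21L^2),
                    embedder = embedder, USE.NAMES = FALSE))
    name <- embedder
  }
  if (any(!is.finite(vec)))
    stop("non-finite protein embedding for task '", task$task_id, "'")
  structure(list(task_id = task$task_id, vectors = vec, embedder_name = name),
            class = "protein_embedding")
}
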