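#' Construct a bioactivity task
#'
#' A task is the unit of all distance and hardness computation: an ordered set
#' of molecules with binary activity labels (the data) plus zero or more
#' protein sequences (the metadata). Tasks play one of two roles: `source`
#' tasks are available for knowledge sharing, `target` tasks are the held-out
#' tasks whose hardness is being quantified.
#'
#' @param task_id Unique string identifier.
#' @param molecules Character vector of SMILES strings (or surrogate molecule
#'   identifiers when a precomputed feature matrix is attached).
#' @param labels Integer/numeric vector of the same length as `molecules`;
#'   1 = active, 0 = inactive.
#' @param proteins Character vector of amino-acid sequences (single-letter
#'   code); may be empty. A multi-record set represents a protein complex.
#' @param role `"source"` or `"target"`.
#' @param features Optional numeric matrix with one row per molecule:
#'   precomputed molecule embeddings consumed by the `"loaded"` featurizer.
#' @param protein_ids Optional accession strings, one per protein.
#' @return An object of class `bioactivity_task`.
#' @export
bioactivity_task <- function(task_id, molecules, labels,
                             proteins = character(),
                             role = c("source", "target"),
                             features = NULL, protein_ids = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(task_id), length(task_id) == 1L, nzchar(task_id))
  molecules <- as.character(molecules)
  labels <- as.integer(labels)
  if (length(labels) != length(molecules))
    stop("task '", task_id, "': labels (", length(labels),
         ") and molecules (", length(molecules), ") differ in length")
  bad <- which(!labels %in% c(0L, 1L) | is.na(labels))
  if (length(bad))
    stop("task '", task_id, "': labels outside {0,1} at rows ",
         paste(bad, collapse = ", "))
  proteins <- toupper(as.character(proteins))
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != length(molecules))
      stop("task '", task_id, "': feature matrix has ", nrow(features),
           " rows for ", length(molecules), " molecules")
    if (any(!is.finite(features)))
      stop("task '", task_id, "': non-finite feature values")
  }
  if (!is.null(protein_ids) && length(protein_ids) != length(proteins))
    stop("task '", task_id, "': protein_ids length mismatch")
  structure(
    list(task_id = task_id, molecules = molecules, labels = labels,
         proteins = proteins,
         protein_ids = protein_ids %||%
           if (length(proteins)) paste0(task_id, "_P", seq_along(proteins))
           else character(),
         role = role, features = features),
    class = "bioactivity_task")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bioactivity_task <- function(x, ...) {
  cat("<bioactivity_task> ", x$task_id, " (", x$role, ")\n",
      "  molecules: ", length(x$molecules),
      " (", sum(x$labels == 1L), " active / ",
      sum(x$labels == 0L), " inactive)\n",
      "  proteins:  ", length(x$proteins), "\n",
      if (!is.null(x$features))
        paste0("  features:  ", nrow(x$features), " x ", ncol(x$features), "\n")
      else "", sep = "")
  invisible(x)
}

#' Validate the SMILES strings of a task
#'
#' Each molecule is parsed with the chemistry toolkit; unparseable records are
#' reported with their row numbers. Tasks carrying a precomputed feature
#' matrix use surrogate molecule identifiers and are not SMILES-validated.
#'
#' @param task A [bioactivity_task()].
#' @return `task`, invisibly, if valid; otherwise an error listing offending
#'   rows.
#' @export
validate_task_smiles <- function(task) {
  stopifnot(inherits(task, "bioactivity_task"))
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SMILES validation requires the ChemmineR package")
  ok <- vapply(task$molecules, function(s) {
    !inherits(try(suppressWarnings(ChemmineR::smiles2sdf(s)), silent = TRUE),
              "try-error")
  }, logical(1), USE.NAMES = FALSE)
  if (!all(ok))
    stop("task '", task$task_id, "': unparseable SMILES at rows ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(task$molecules[!ok], collapse = ", "))
  invisible(task)
}

#' Load a task from a directory
#'
#' Reads the on-disk task layout: `molecules.csv` with columns `smiles,label`
#' (required), `protein.fasta` (optional; multi-record = protein complex) and
#' `features.csv` (optional precomputed molecule embedding matrix, one row per
#' molecule). Molecule order is preserved from the file, proteins from FASTA
#' order. When `features.csv` is present the molecule column may hold
#' surrogate identifiers and SMILES validation is skipped.
#'
#' @param path Task directory.
#' @param role Task role, `"source"` or `"target"`.
#' @param validate Validate SMILES with the chemistry toolkit (default `TRUE`
#'   when no feature matrix is present).
#' @return A [bioactivity_task()].
#' @export
load_task <- function(path, role = c("source", "target"), validate = NULL) {
  role <- match.arg(role)
  mol_file <- file.path(path, "molecules.csv")
  if (!file.exists(mol_file))
    stop("no molecules.csv in ", path)
  tab <- utils::read.csv(mol_file, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric"))
  if (!all(c("smiles", "label") %in% names(tab)))
    stop(mol_file, ": expected header 'smiles,label'")
  fasta <- file.path(path, "protein.fasta")
  proteins <- character(); protein_ids <- NULL
  if (file.exists(fasta)) {
    fr <- read_fasta(fasta)
    proteins <- unname(fr); protein_ids <- names(fr)
  }
  feat_file <- file.path(path, "features.csv")
  features <- NULL
  if (file.exists(feat_file)) {
    features <- as.matrix(utils::read.csv(feat_file, header = FALSE))
    dimnames(features) <- NULL
  }
  task <- bioactivity_task(basename(normalizePath(path, mustWork = FALSE)),
                           tab$smiles, tab$label, proteins, role,
                           features = features, protein_ids = protein_ids)
  if (is.null(validate)) validate <- is.null(features)
  if (validate) validate_task_smiles(task)
  task
}

#' Write a task to a directory
#'
#' Inverse of [load_task()]: emits `molecules.csv`, `protein.fasta` (if the
#' task has proteins) and `features.csv` (if the task carries a feature
#' matrix).
#'
#' @param task A [bioactivity_task()].
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "bioactivity_task"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(smiles = task$molecules, label = task$labels),
                   file.path(path, "molecules.csv"), row.names = FALSE,
                   quote = FALSE)
  if (length(task$proteins))
    write_fasta(setNames(task$proteins, task$protein_ids),
                file.path(path, "protein.fasta"))
  if (!is.null(task$features))
    utils::write.table(task$features, file.path(path, "features.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop(path, ": not a FASTA file")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids)
}

write_fasta <- function(seqs, path) {
  out <- character(0)
  for (i in seq_along(seqs))
    out <- c(out, paste0(">", names(seqs)[i]),
             gsub("(.{60})", "\\1\n", seqs[[i]], perl = TRUE))
  writeLines(sub("\n$", "", out), path)
}

#' Construct a source-by-target distance matrix
#'
#' Rows index source tasks, columns index target tasks (the field convention
#' for source/target distance tables).
#'
#' @param values Non-negative, finite numeric matrix, `n_sources` x
#'   `n_targets`.
#' @param source_ids,target_ids Task identifiers for rows / columns.
#' @param space `"chem"` or `"prot"`.
#' @param metadata Named list (featurizer, metric, solver, seed, ...),
#'   serialized alongside the matrix.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, source_ids, target_ids,
                            space = c("chem", "prot"), metadata = list()) {
  space <- match.arg(space)
  values <- as.matrix(values)
  source_ids <- as.character(source_ids)
  target_ids <- as.character(target_ids)
  if (length(source_ids) == 0L || length(target_ids) == 0L)
    stop("degenerate distance matrix: empty source or target id list")
  if (nrow(values) != length(source_ids) || ncol(values) != length(target_ids))
    stop("distance matrix shape (", nrow(values), "x", ncol(values),
         ") does not match id lists (", length(source_ids), "x",
         length(target_ids), ")")
  if (anyDuplicated(source_ids) || anyDuplicated(target_ids))
    stop("duplicated task ids in distance matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("distance matrix entries must be finite and >= 0")
  dimnames(values) <- list(source_ids, target_ids)
  structure(list(values = values, source_ids = source_ids,
                 target_ids = target_ids, space = space, metadata = metadata),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> space=", x$space, ", ",
      length(x$source_ids), " sources x ", length(x$target_ids),
      " targets\n", sep = "")
  invisible(x)
}

#' Write / read a distance matrix
#'
#' CSV layout: first column `source_id`, remaining columns headed by target
#' task ids. A JSON sidecar `<path>.meta.json` stores the space and metadata.
#'
#' @param m A [distance_matrix()].
#' @param path CSV file path.
#' @return `write_distance_matrix`: `path` invisibly;
#'   `read_distance_matrix`: the reconstructed [distance_matrix()].
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(inherits(m, "distance_matrix"))
  df <- data.frame(source_id = m$source_ids, m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(c(list(space = m$space), m$metadata),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "source_id" || ncol(df) < 2L)
    stop(path, ": expected a 'source_id' column plus >=1 target column")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  space <- meta$space %||% "chem"
  meta$space <- NULL
  vals <- as.matrix(df[, -1, drop = FALSE])
  distance_matrix(vals, df$source_id, colnames(df)[-1], space = space,
                  metadata = meta)
}
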