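#' Run configuration for the full pipeline
#'
#' Resolves and validates every setting before any compute starts. The
#' configuration (and its hash) is serialized with every output so artifacts
#' from different configurations cannot be mixed silently.
#'
#' @param tasks_dir Directory holding `sources/` and `targets/` task
#'   directories; `NULL` means generate the synthetic universe of
#'   `universe`.
#' @param universe A [universe_config()] used when `tasks_dir` is `NULL`.
#' @param featurizer Molecule featurizer name.
#' @param standardize Standardize features pooled over all tasks (default:
#'   only for `desc2d`).
#' @param otdd An [otdd_config()].
#' @param hardness A [hardness_config()].
#' @param encoder An [encoder_config()].
#' @param support_size Episode support size for the evaluation stage.
#' @param eval_seeds Episode draws averaged per task in evaluation.
#' @param seed Global seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(tasks_dir = NULL, universe = universe_config(),
                       featurizer = "loaded", standardize = NULL,
                       otdd = otdd_config(), hardness = hardness_config(),
                       encoder = encoder_config(), support_size = 16L,
                       eval_seeds = 5L, seed = 1L) {
  standardize <- standardize %||% identical(featurizer, "desc2d")
  structure(list(tasks_dir = tasks_dir, universe = universe,
                 featurizer = featurizer, standardize = standardize,
                 otdd = otdd, hardness = hardness, encoder = encoder,
                 support_size = as.integer(support_size),
                 eval_seeds = as.integer(eval_seeds),
                 seed = as.integer(seed)),
            class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full hardness pipeline
#'
#' Executes the stages in dependency order — load or simulate tasks,
#' featurize, chemical-space distances (OTDD), protein-space distances,
#' hardness report, prototypical-network evaluation against the random-forest
#' baseline, hardness-gain correlation — writing each stage's artifact into
#' `out_dir` and skipping stages whose artifact already exists under the same
#' configuration hash.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory artifacts (`universe`,
#'   `chem_dm`, `prot_dm`, `report`, `eval`, `correlation`, `timings`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  hash_file <- file.path(out_dir, "config_hash.txt")
  if (file.exists(hash_file) && !identical(readLines(hash_file, n = 1L),
                                           hash))
    stop("output directory ", out_dir, " holds artifacts from a different ",
         "configuration; refusing to mix")
  writeLines(hash, hash_file)
  jsonlite::write_json(list(hash = hash,
                            config = rapply(unclass(config), unclass,
                                            how = "replace")),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  say <- function(...) if (!quiet) message("[taskhardness] ", ...)
  timings <- list()
  stage <- function(name, file, compute, read, write) {
    path <- file.path(out_dir, file)
    if (file.exists(path)) {
      say("stage ", name, ": cached (", file, ")")
      return(read(path))
    }
    t0 <- Sys.time()
    res <- compute()
    write(res, path)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                            units = "secs"))
    say("stage ", name, ": ", sprintf("%.1fs", timings[[name]]))
    res
  }

  # tasks
  if (is.null(config$tasks_dir)) {
    say("stage simulate: universe seed ", config$universe$seed)
    universe <- generate_universe(config$universe)
  } else {
    say("stage load: ", config$tasks_dir)
    load_dir <- function(sub, role) {
      dirs <- list.dirs(file.path(config$tasks_dir, sub),
                        recursive = FALSE)
      lapply(dirs, function(dd) {
        t <- load_task(dd, role = role)
        pv <- file.path(dd, "protein_vectors.csv")
        if (file.exists(pv)) {
          t$protein_vectors <- as.matrix(utils::read.csv(pv,
                                                         header = FALSE))
          dimnames(t$protein_vectors) <- NULL
        }
        t
      })
    }
    universe <- list(sources = load_dir("sources", "source"),
                     targets = load_dir("targets", "target"),
                     truth = NULL, cfg = NULL)
  }

  # featurize
  feat <- function(tasks) lapply(tasks, featurize_molecules,
                                 featurizer = config$featurizer)
  src_ds <- feat(universe$sources)
  tgt_ds <- feat(universe$targets)
  if (config$standardize) {
    std <- standardize_features(c(src_ds, tgt_ds))
    src_ds <- std$datasets[seq_along(src_ds)]
    tgt_ds <- std$datasets[length(src_ds) + seq_along(tgt_ds)]
  }

  chem_dm <- stage("chem-distance", "chem_distance.csv",
                   function() chem_distance_matrix(src_ds, tgt_ds,
                                                   config$otdd),
                   read_distance_matrix, write_distance_matrix)
  prot_dm <- stage("prot-distance", "prot_distance.csv",
                   function() prot_distance_matrix(universe$sources,
                                                   universe$targets),
                   read_distance_matrix, write_distance_matrix)
  report <- stage("hardness", "hardness_report.csv",
                  function() compute_hardness(chem_dm, prot_dm, tgt_ds,
                                              src_ds, config$hardness,
                                              featurizer = "loaded"),
                  read_hardness_report, write_hardness_report)

  # meta-learner vs baseline
  eval_file <- file.path(out_dir, "eval_records.csv")
  if (file.exists(eval_file)) {
    say("stage protonet-eval: cached")
    edf <- utils::read.csv(eval_file, stringsAsFactors = FALSE)
  } else {
    t0 <- Sys.time()
    enc <- train_protonet(src_ds, encoder_cfg = config$encoder,
                          seed = config$seed)
    recs <- list()
    for (ds in tgt_ds) {
      recs[[length(recs) + 1L]] <-
        evaluate_task("protonet", ds, support_size = config$support_size,
                      encoder = enc, n_seeds = config$eval_seeds,
                      seed = config$seed, cfg = config$hardness)
      recs[[length(recs) + 1L]] <-
        evaluate_task("rf", ds, support_size = config$support_size,
                      n_seeds = config$eval_seeds, seed = config$seed,
                      cfg = config$hardness)
    }
    edf <- do.call(rbind, lapply(recs, function(r)
      data.frame(task_id = r$task_id, method = r$method,
                 support_size = r$support_size, roc_auc = r$roc_auc,
                 auprc = r$auprc, n_episodes = r$n_episodes)))
    utils::write.csv(edf, eval_file, row.names = FALSE)
    timings[["protonet-eval"]] <- as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))
    say("stage protonet-eval: ",
        sprintf("%.1fs", timings[["protonet-eval"]]))
  }

  to_records <- function(df) lapply(seq_len(nrow(df)), function(i)
    structure(as.list(df[i, ]), class = "eval_record"))
  meta <- to_records(edf[edf$method == "protonet", ])
  base <- to_records(edf[edf$method == "rf", ])
  corr <- hardness_gain_correlation(report, meta, base)
  jsonlite::write_json(corr[c("pearson", "spearman", "pearson_absolute",
                              "n", "metric")],
                       file.path(out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  say("hardness-gain correlation: Pearson ",
      sprintf("%.3f", corr$pearson), " (n=", corr$n, ")")
  invisible(list(universe = universe, chem_dm = chem_dm, prot_dm = prot_dm,
                 report = report, eval = edf, correlation = corr,
                 timings = timings))
}
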