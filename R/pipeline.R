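## Pipeline stages with pure file interfaces: fixtures -> score -> validate
## -> analyze. Each stage reads and writes the documented interchange formats
## (compound lists, JSON-lines training/scored lists, CSV tables) and records
## a run manifest, so outputs produced by external tools can be slotted in at
## any stage boundary.

.schema_version <- "fpbench/1"

.write_manifest <- function(dir, stage, inputs, outputs, seed = NULL) {
  man <- list(
    schema = .schema_version, stage = stage,
    tool_version = as.character(utils::packageVersion("fpbench")),
    seed = seed, inputs = inputs, outputs = outputs,
    config_digests = lapply(inputs[grepl("config", names(inputs))],
                            function(p) if (file.exists(p))
                              unname(tools::md5sum(p)) else NA_character_),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Generate fixture targets and write them in the platform formats
#'
#' @param out_dir output directory; per target, writes
#'   `<id>_actives.smi`, `<id>_decoys.smi` and `<id>_training.jsonl`.
#' @param recipes list of `fixture_recipe` objects (one target each).
#' @param n_queries,decoy_fraction,repetitions training-list parameters
#'   (defaults 5, 0.20, 50).
#' @param seed integer master seed for the training-list sampling.
#' @return character vector of target IDs, invisibly.
#' @export
run_fixtures <- function(out_dir, recipes, n_queries = 5L,
                         decoy_fraction = 0.20, repetitions = 50L,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(seq_along(recipes), function(i) {
    ds <- generate_target(recipes[[i]])
    ds$training <- generate_training_lists(
      ds, n_queries = n_queries, decoy_fraction = decoy_fraction,
      repetitions = repetitions, seed = .sub_seed(seed, ds$target_id, i))
    write_compound_list(ds$actives,
                        file.path(out_dir, paste0(ds$target_id, "_actives.smi")))
    write_compound_list(ds$decoys,
                        file.path(out_dir, paste0(ds$target_id, "_decoys.smi")))
    write_training_lists(ds$training,
                         file.path(out_dir, paste0(ds$target_id,
                                                   "_training.jsonl")))
    ds$target_id
  }, character(1))
  .write_manifest(out_dir, "fixtures",
                  inputs = list(), outputs = as.list(ids), seed = seed)
  invisible(ids)
}

.load_target <- function(dir, target_id, check_smiles = TRUE) {
  act <- read_compound_list(file.path(dir, paste0(target_id, "_actives.smi")),
                            "active", check_smiles = check_smiles)
  dec <- read_compound_list(file.path(dir, paste0(target_id, "_decoys.smi")),
                            "decoy", check_smiles = check_smiles)
  ds <- target_dataset(target_id, act, dec)
  tr_path <- file.path(dir, paste0(target_id, "_training.jsonl"))
  if (file.exists(tr_path)) ds$training <- read_training_lists(tr_path, ds)
  ds
}

#' Discover target IDs in a fixtures directory
#' @param dir directory written by [run_fixtures()].
#' @return character vector of target IDs.
#' @export
list_targets <- function(dir) {
  f <- list.files(dir, pattern = "_actives\\.smi$")
  sub("_actives\\.smi$", "", f)
}

#' Stage 1: score all targets of a fixtures directory
#'
#' For every target and every fingerprint of the config, ranks each
#' repetition's test set by MAX-fusion similarity to the query actives and
#' streams the scored lists to one JSON-lines file per target.
#'
#' @param in_dir directory with compound and training lists.
#' @param out_dir output directory for scored lists
#'   (`<target>_scores.jsonl`).
#' @param fingerprint_config path to the fingerprint-names file (the `-f`
#'   argument).
#' @param measure similarity measure name (`-s`, default `"Dice"`).
#' @param append append to existing score files (`-a`) instead of
#'   overwriting.
#' @param seed master seed (tie-break policy).
#' @param targets optional subset of target IDs.
#' @return invisibly, the paths of the written score files.
#' @export
run_score <- function(in_dir, out_dir, fingerprint_config, measure = "Dice",
                      append = FALSE, seed = 1L, targets = NULL) {
  descriptors <- load_fingerprint_config(fingerprint_config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(targets)) targets <- list_targets(in_dir)
  if (length(targets) == 0L) stop("no targets found in '", in_dir, "'",
                                  call. = FALSE)
  paths <- vapply(targets, function(tid) {
    ds <- .load_target(in_dir, tid)
    if (is.null(ds$training))
      stop("target '", tid, "' has no training lists", call. = FALSE)
    path <- file.path(out_dir, paste0(tid, "_scores.jsonl"))
    first <- !append
    for (desc in descriptors) {
      res <- score_target(ds, desc, measure = measure, seed = seed)
      write_scored_lists(res, path, append = !first)
      first <- FALSE
    }
    path
  }, character(1))
  .write_manifest(out_dir, "score",
                  inputs = list(in_dir = in_dir,
                                fingerprint_config = fingerprint_config,
                                measure = measure),
                  outputs = as.list(unname(paths)), seed = seed)
  invisible(unname(paths))
}

#' Stage 2: validate scored lists with the configured evaluation methods
#'
#' Computes every metric for every (target, fingerprint, repetition) and the
#' within-repetition fingerprint ranks, and writes one long-format CSV.
#'
#' @param in_paths score files (or a directory containing
#'   `*_scores.jsonl`), the `-i` argument.
#' @param out_path output CSV path (`-o`).
#' @param methods_config path to the evaluation-methods file (`-m`), one
#'   `NAME parameter` pair per line.
#' @param ignore_fingerprints optional path to a file naming fingerprints to
#'   ignore (`-r`), one per line.
#' @return the evaluation data.frame, invisibly.
#' @export
run_validate <- function(in_paths, out_path, methods_config,
                         ignore_fingerprints = NULL) {
  methods <- load_metric_config(methods_config)
  if (length(in_paths) == 1L && dir.exists(in_paths))
    in_paths <- list.files(in_paths, pattern = "_scores\\.jsonl$",
                           full.names = TRUE)
  if (length(in_paths) == 0L) stop("no score files given", call. = FALSE)
  drop <- character(0)
  if (!is.null(ignore_fingerprints) && file.exists(ignore_fingerprints)) {
    drop <- trimws(readLines(ignore_fingerprints, warn = FALSE))
    drop <- drop[nzchar(drop) & !startsWith(drop, "#")]
  }
  results <- unlist(lapply(in_paths, read_scored_lists), recursive = FALSE)
  if (length(drop))
    results <- Filter(function(r) !(r$fingerprint %in% drop), results)
  values <- evaluate(results, methods)
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(values, out_path, row.names = FALSE)
  .write_manifest(dirname(out_path), "validate",
                  inputs = list(in_paths = paste(in_paths, collapse = ";"),
                                methods_config = methods_config),
                  outputs = list(out_path))
  invisible(values)
}

#' Stage 3: analysis across targets
#'
#' From the validation CSV, writes per-target average-performance tables,
#' the average rank of every fingerprint per method, and (per method) the
#' post-hoc pairwise test file with the bootstrap-resampled adjusted
#' p-values and the three-class significance matrix.
#'
#' @param in_path validation CSV from [run_validate()] (`-i`).
#' @param out_dir output directory (`-o`).
#' @param alpha confidence level for the significance calls (default 0.05).
#' @param n_boot bootstrap replicates for the post-hoc tests (default 100).
#' @param n_adjust_resamples maxT sign-flip resamples (default 1000).
#' @param seed master seed for the resampling.
#' @param posthoc run the post-hoc pairwise tests (default TRUE; they are
#'   flagged exploratory when the global test is not significant).
#' @return invisibly, a list with `averages`, `avg_ranks`, `global`,
#'   `pairwise` (per method).
#' @export
run_analyze <- function(in_path, out_dir, alpha = 0.05, n_boot = 100L,
                        n_adjust_resamples = 1000L, seed = 1L,
                        posthoc = TRUE) {
  values <- utils::read.csv(in_path, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  avg <- average_performance(values)
  utils::write.csv(avg, file.path(out_dir, "average_performance.csv"),
                   row.names = FALSE)
  methods <- unique(values$method)
  multi_target <- length(unique(values$target)) >= 2L
  avg_ranks <- list(); global <- list(); pairwise <- list()
  rank_rows <- list()
  for (m in methods) {
    rm_ <- rank_matrix(values, m)
    ar <- average_rank(rm_)
    avg_ranks[[m]] <- ar
    rank_rows[[m]] <- data.frame(method = m, fingerprint = names(ar),
                                 average_rank = unname(ar),
                                 stringsAsFactors = FALSE)
    if (multi_target && dim(rm_)[3] >= 2L) {
      global[[m]] <- friedman_global(rm_)
      if (posthoc) {
        rep_ <- posthoc_pairwise(rm_, alpha = alpha, n_boot = n_boot,
                                 n_adjust_resamples = n_adjust_resamples,
                                 seed = seed,
                                 global_significant =
                                   global[[m]]$p_value < alpha)
        pairwise[[m]] <- rep_
        utils::write.csv(as.data.frame(rep_),
                         file.path(out_dir, sprintf("pairwise_%s.csv",
                                                    gsub("[^A-Za-z0-9]", "_", m))),
                         row.names = FALSE)
        padj <- attr(rep_, "adjusted_p")
        colnames(padj) <- sprintf("boot%03d", seq_len(ncol(padj)))
        utils::write.csv(
          cbind(rep_[, c("fp_a", "fp_b")], as.data.frame(padj)),
          file.path(out_dir, sprintf("pvalues_%s.csv",
                                     gsub("[^A-Za-z0-9]", "_", m))),
          row.names = FALSE)
        cm <- category_matrix(rep_, ar)
        utils::write.csv(cm,
                         file.path(out_dir, sprintf("categories_%s.csv",
                                                    gsub("[^A-Za-z0-9]", "_", m))))
      }
    }
  }
  utils::write.csv(do.call(rbind, rank_rows),
                   file.path(out_dir, "average_rank.csv"), row.names = FALSE)
  if (length(global)) {
    gdf <- data.frame(method = names(global),
                      statistic = vapply(global, `[[`, 0, "statistic"),
                      df = vapply(global, `[[`, 0, "df"),
                      p_value = vapply(global, `[[`, 0, "p_value"))
    utils::write.csv(gdf, file.path(out_dir, "friedman_global.csv"),
                     row.names = FALSE)
  }
  .write_manifest(out_dir, "analyze", inputs = list(in_path = in_path),
                  outputs = list(out_dir), seed = seed)
  invisible(list(averages = avg, avg_ranks = avg_ranks, global = global,
                 pairwise = pairwise))
}
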