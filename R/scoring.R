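## Stage 1 (scoring): rank each repetition's test set by MAX-fusion
## similarity of the test molecules to the query actives.

#' Construct a ranked screening result
#'
#' @param target_id,fingerprint,repetition identifiers of the run.
#' @param similarity numeric scores, already in non-increasing order.
#' @param internal_id compound IDs parallel to `similarity`.
#' @param is_active logical labels parallel to `similarity`.
#' @return object of class `ranked_screen_result`.
#' @export
ranked_screen_result <- function(target_id, fingerprint, repetition,
                                 similarity, internal_id, is_active) {
  stopifnot(length(similarity) == length(internal_id),
            length(similarity) == length(is_active),
            !is.unsorted(rev(similarity)))
  structure(list(target_id = target_id, fingerprint = fingerprint,
                 repetition = as.integer(repetition),
                 similarity = as.numeric(similarity),
                 internal_id = as.character(internal_id),
                 is_active = as.logical(is_active)),
            class = "ranked_screen_result")
}

#' @export
print.ranked_screen_result <- function(x, ...) {
  cat(sprintf("<ranked_screen_result> %s / %s rep %d: %d molecules, %d active\n",
              x$target_id, x$fingerprint, x$repetition,
              length(x$similarity), sum(x$is_active)))
  invisible(x)
}

# deterministic per-(seed, target, repetition) sub-seed below 2^31
.sub_seed <- function(seed, target_id, repetition, stage = 0L) {
  h <- .hash_ints(c(seed, utf8ToInt(as.character(target_id)),
                    repetition + 1L, stage))
  as.integer(h %% 2147483629)
}

#' Score a target: rank test molecules against query actives
#'
#' For every repetition in the dataset's training lists, the test set (all
#' actives except the queries, all decoys except the training decoys) is
#' scored by MAX-fusion similarity to the query actives and sorted. Ties in
#' similarity are broken by a seeded pseudo-random key derived from
#' (seed, target, repetition, internal ID), shared across fingerprints of a
#' repetition, so tie handling is deterministic, unbiased, identical across
#' fingerprints, and invariant to the input order of the compound lists.
#'
#' Molecules flagged as unparsable are excluded from scoring (with their
#' count reported via a message), never silently re-labelled.
#'
#' @param dataset a `target_dataset` with training lists.
#' @param descriptor an `fp_descriptor` or fingerprint name.
#' @param measure similarity measure name (default `"Dice"`).
#' @param seed integer master seed governing tie-breaking.
#' @return list of `ranked_screen_result`, one per repetition.
#' @export
score_target <- function(dataset, descriptor, measure = "Dice", seed = 1L) {
  stopifnot(inherits(dataset, "target_dataset"))
  if (is.null(dataset$training) || length(dataset$training) == 0L)
    stop("dataset has no training lists", call. = FALSE)
  if (is.character(descriptor)) descriptor <- fingerprint_descriptor(descriptor)

  ok_act <- dataset$actives$smiles_ok
  ok_dec <- dataset$decoys$smiles_ok
  n_bad <- sum(!ok_act) + sum(!ok_dec)
  if (n_bad > 0L)
    message(sprintf("score_target(%s): %d unparsable molecule(s) excluded",
                    dataset$target_id, n_bad))

  # fingerprints computed once per molecule and shared across repetitions
  fp_act <- compute_fingerprints(dataset$actives$smiles, descriptor)
  fp_dec <- compute_fingerprints(dataset$decoys$smiles, descriptor)

  lapply(dataset$training, function(tl) {
    qa_idx <- match(tl$query_actives$index, dataset$actives$index)
    td_idx <- match(tl$training_decoys$index, dataset$decoys$index)
    test_a <- setdiff(seq_len(nrow(dataset$actives)), qa_idx)
    test_d <- setdiff(seq_len(nrow(dataset$decoys)), td_idx)
    test_a <- test_a[ok_act[test_a]]
    test_d <- test_d[ok_dec[test_d]]
    if (length(test_a) == 0L)
      stop(sprintf("repetition %d of target %s has no valid test actives",
                   tl$repetition, dataset$target_id), call. = FALSE)
    queries <- fp_act[qa_idx]
    queries <- Filter(Negate(is.null), queries)
    if (length(queries) == 0L)
      stop(sprintf("repetition %d of target %s has no valid query actives",
                   tl$repetition, dataset$target_id), call. = FALSE)
    test_fp <- c(fp_act[test_a], fp_dec[test_d])
    ids <- c(dataset$actives$internal_id[test_a],
             dataset$decoys$internal_id[test_d])
    lab <- c(rep(TRUE, length(test_a)), rep(FALSE, length(test_d)))
    sims <- bulk_max_similarity(queries, test_fp, measure)
    # seeded tie-break: each molecule gets a pseudo-random key from
    # (seed, target, repetition, internal ID), shared across fingerprints.
    # Keying on identity (not list position) makes the ordering invariant
    # to permutations of the input lists.
    rep_salt <- .sub_seed(seed, dataset$target_id, tl$repetition)
    tie_key <- vapply(ids, function(id) .hash_ints(c(rep_salt, utf8ToInt(id))),
                      numeric(1), USE.NAMES = FALSE)
    ord <- order(-sims, tie_key)
    ranked_screen_result(dataset$target_id, descriptor$name, tl$repetition,
                         sims[ord], ids[ord], lab[ord])
  })
}

## ---- scored-list serialization (JSON-lines) -------------------------------

#' Write ranked screening results as JSON-lines
#'
#' One result (repetition) per line. Similarities are rounded to 6 decimals
#' on disk; in-memory values keep full precision.
#'
#' @param results list of `ranked_screen_result`.
#' @param path output path.
#' @param append append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_scored_lists <- function(results, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (res in results) {
    writeLines(jsonlite::toJSON(list(
      schema = "fpbench/scored/1",
      target = res$target_id, fingerprint = res$fingerprint,
      repetition = res$repetition,
      similarity = round(res$similarity, 6),
      internal_id = res$internal_id,
      is_active = res$is_active), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read ranked screening results from JSON-lines
#'
#' Accepts files produced by [write_scored_lists()] or by external tools
#' emitting the same schema.
#'
#' @param path input path.
#' @return list of `ranked_screen_result`.
#' @export
read_scored_lists <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop(sprintf("line %d of '%s' is not valid JSON: %s", i, path,
                   conditionMessage(e)), call. = FALSE))
    need <- c("target", "fingerprint", "repetition", "similarity",
              "internal_id", "is_active")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop(sprintf("line %d of '%s' lacks field(s): %s", i, path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    ranked_screen_result(x$target, x$fingerprint, x$repetition,
                         x$similarity, x$internal_id, x$is_active)
  })
}
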