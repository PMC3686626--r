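## Compound and training lists: the platform's on-disk formats.
##
## Compound lists are whitespace-separated text (external ID, internal ID,
## SMILES; '#' comments allowed; gzip-transparent). Training lists are
## JSON-lines, one repetition per line. Compound numbering is 0-based and is
## determined by file order.

#' Build an internal compound identifier
#'
#' Internal IDs follow `<dataset>_<targetID>_<A|D>_<number>` where `A` marks
#' actives and `D` decoys, and the number is the 0-based position of the
#' compound within its source list.
#'
#' @param dataset collection name (e.g. `"ChEMBL"`).
#' @param target_id target identifier.
#' @param role `"active"` or `"decoy"`.
#' @param number 0-based compound number(s).
#' @return character vector of internal IDs.
#' @export
make_internal_id <- function(dataset, target_id, role, number) {
  role <- match.arg(role, c("active", "decoy"))
  sprintf("%s_%s_%s_%d", dataset, target_id,
          if (role == "active") "A" else "D", as.integer(number))
}

#' Parse internal compound identifiers
#' @param internal_id character vector of internal IDs.
#' @return data.frame with columns `dataset`, `target_id`, `role`, `number`.
#' @export
parse_internal_id <- function(internal_id) {
  m <- regmatches(internal_id,
                  regexec("^(.+)_([^_]+)_([AD])_([0-9]+)$", internal_id))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("malformed internal ID(s): ",
         paste(internal_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "),
         call. = FALSE)
  data.frame(
    dataset = vapply(m, `[`, "", 2L),
    target_id = vapply(m, `[`, "", 3L),
    role = ifelse(vapply(m, `[`, "", 4L) == "A", "active", "decoy"),
    number = as.integer(vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE)
}

#' Read a compound list
#'
#' Each non-comment line holds at least three whitespace-separated fields:
#' external ID, internal ID, SMILES. Records are returned in file order with
#' a sequential 0-based `index`. SMILES that do not parse are retained but
#' flagged (`smiles_ok = FALSE`) and later excluded from scoring; silently
#' dropping them would change every metric denominator.
#'
#' @param path file path (plain or gzipped text).
#' @param role `"active"` or `"decoy"`, applied to all records.
#' @param check_smiles validate each SMILES with the parser (default TRUE).
#' @return data.frame of class `compound_list` with columns `external_id`,
#'   `internal_id`, `smiles`, `role`, `index`, `smiles_ok`.
#' @export
read_compound_list <- function(path, role, check_smiles = TRUE) {
  role <- match.arg(role, c("active", "decoy"))
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)   # gzip handled transparently
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- data.frame(external_id = character(0), internal_id = character(0),
                      smiles = character(0), role = character(0),
                      index = integer(0), smiles_ok = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("compound_list", "data.frame")
    return(out)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L))
    stop(sprintf("malformed compound line %d in '%s': expected >= 3 fields",
                 lineno[which(nf < 3L)[1]], path), call. = FALSE)
  out <- data.frame(
    external_id = vapply(fields, `[`, "", 1L),
    internal_id = vapply(fields, `[`, "", 2L),
    smiles = vapply(fields, `[`, "", 3L),
    role = role,
    index = seq_along(fields) - 1L,
    stringsAsFactors = FALSE)
  if (check_smiles) {
    out$smiles_ok <- vapply(out$smiles, function(s)
      !is.null(suppressWarnings(parse_smiles(s))), logical(1),
      USE.NAMES = FALSE)
    nbad <- sum(!out$smiles_ok)
    if (nbad > 0L)
      warning(sprintf("%d of %d SMILES in '%s' failed to parse; %s",
                      nbad, nrow(out), path,
                      "records kept but excluded from scoring"),
              call. = FALSE)
  } else {
    out$smiles_ok <- TRUE
  }
  class(out) <- c("compound_list", "data.frame")
  out
}

#' Write a compound list
#' @param records a `compound_list` data.frame.
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_compound_list <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s %s %s", records$external_id, records$internal_id,
                     records$smiles), con)
  invisible(path)
}

#' Assemble a target dataset
#'
#' @param target_id target identifier.
#' @param actives,decoys `compound_list` data.frames with roles `"active"`
#'   and `"decoy"`.
#' @param training optional list of training lists (see
#'   [generate_training_lists()]).
#' @return object of class `target_dataset`.
#' @export
target_dataset <- function(target_id, actives, decoys, training = NULL) {
  stopifnot(all(actives$role == "active"), all(decoys$role == "decoy"))
  structure(list(target_id = target_id, actives = actives, decoys = decoys,
                 training = training), class = "target_dataset")
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf("<target_dataset %s> %d actives, %d decoys, %s training lists\n",
              x$target_id, nrow(x$actives), nrow(x$decoys),
              if (is.null(x$training)) "no" else length(x$training)))
  invisible(x)
}

#' Generate training lists for repeated virtual-screening runs
#'
#' For each repetition, samples (without replacement) `n_queries` actives as
#' query molecules and `round(decoy_fraction * n_decoys)` decoys as training
#' decoys; the remaining molecules form the test set. Reproducible for a
#' fixed seed.
#'
#' @param dataset a `target_dataset`.
#' @param n_queries number of query actives per repetition (default 5).
#' @param decoy_fraction fraction of decoys used for training (default 0.20).
#' @param repetitions number of repetitions (default 50).
#' @param seed integer master seed.
#' @return list of `repetitions` training lists, each a list with fields
#'   `repetition` (0-based), `query_actives` and `training_decoys`
#'   (data.frames with `internal_id`, `index`).
#' @export
generate_training_lists <- function(dataset, n_queries = 5L,
                                    decoy_fraction = 0.20,
                                    repetitions = 50L, seed = 1L) {
  stopifnot(inherits(dataset, "target_dataset"))
  na <- nrow(dataset$actives); nd <- nrow(dataset$decoys)
  if (n_queries >= na)
    stop(sprintf("n_queries (%d) must be smaller than the number of actives (%d)",
                 n_queries, na), call. = FALSE)
  if (decoy_fraction <= 0 || decoy_fraction >= 1)
    stop("decoy_fraction must lie strictly between 0 and 1", call. = FALSE)
  n_tdec <- round(decoy_fraction * nd)
  if (n_tdec < 1L)
    stop("decoy_fraction selects no training decoys", call. = FALSE)
  out <- with_seed(seed, {
    lapply(seq_len(repetitions) - 1L, function(rep0) {
      qa <- sort(sample.int(na, n_queries))
      td <- sort(sample.int(nd, n_tdec))
      list(repetition = rep0,
           query_actives = data.frame(
             internal_id = dataset$actives$internal_id[qa],
             index = dataset$actives$index[qa], stringsAsFactors = FALSE),
           training_decoys = data.frame(
             internal_id = dataset$decoys$internal_id[td],
             index = dataset$decoys$index[td], stringsAsFactors = FALSE))
    })
  })
  out
}

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write training lists as JSON-lines
#'
#' One repetition per line; lossless round-trip with
#' [read_training_lists()].
#'
#' @param training list of training lists.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_lists <- function(training, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tl in training) {
    writeLines(jsonlite::toJSON(list(
      repetition = tl$repetition,
      query_actives = tl$query_actives,
      training_decoys = tl$training_decoys), auto_unbox = TRUE,
      digits = NA), con)
  }
  invisible(path)
}

#' Read training lists from JSON-lines
#'
#' @param path input path.
#' @param dataset optional `target_dataset`; when given, every referenced
#'   index is validated against the compound lists.
#' @return list of training lists.
#' @export
read_training_lists <- function(path, dataset = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    qa <- as.data.frame(x$query_actives, stringsAsFactors = FALSE)
    td <- if (length(x$training_decoys))
      as.data.frame(x$training_decoys, stringsAsFactors = FALSE)
    else data.frame(internal_id = character(0), index = integer(0))
    list(repetition = as.integer(x$repetition),
         query_actives = qa, training_decoys = td)
  })
  if (!is.null(dataset)) {
    for (tl in out) {
      if (any(!(tl$query_actives$index %in% dataset$actives$index)))
        stop(sprintf("training list %d references an active index not in %s",
                     tl$repetition, "the compound list"), call. = FALSE)
      if (nrow(tl$training_decoys) &&
          any(!(tl$training_decoys$index %in% dataset$decoys$index)))
        stop(sprintf("training list %d references a decoy index not in %s",
                     tl$repetition, "the compound list"), call. = FALSE)
      both <- intersect(tl$query_actives$internal_id,
                        tl$training_decoys$internal_id)
      if (length(both))
        stop("internal ID(s) appear as both query active and training decoy: ",
             paste(both, collapse = ", "), call. = FALSE)
    }
  }
  out
}
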