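## Validation metrics for ranked screening results: ROC AUC, enrichment
## factor (EF), robust initial enhancement (RIE) and BEDROC.
##
## Throughout, n is the number of actives in the test set, N the total number
## of test molecules and r_i the 1-based rank of the i-th active.

#' Ranked activity labels
#'
#' Container for the ordered active/inactive labels of one ranked screening
#' list (position 1 = best-scored molecule).
#'
#' @param labels logical vector, `TRUE` for actives, in rank order.
#' @return object of class `ranked_labels` with fields `labels`, `n`
#'   (actives), `N` (total) and `ranks` (1-based active ranks).
#' @export
ranked_labels <- function(labels) {
  labels <- as.logical(labels)
  stopifnot(length(labels) >= 2L, !anyNA(labels))
  n <- sum(labels); N <- length(labels)
  if (n == 0L || n == N)
    stop("metrics are undefined when all or no molecules are active",
         call. = FALSE)
  structure(list(labels = labels, n = n, N = N, ranks = which(labels)),
            class = "ranked_labels")
}

#' @export
print.ranked_labels <- function(x, ...) {
  cat(sprintf("<ranked_labels> %d actives / %d molecules\n", x$n, x$N))
  invisible(x)
}

.as_ranked <- function(r) {
  if (inherits(r, "ranked_labels")) r else ranked_labels(r)
}

#' Area under the ROC curve of a ranked list
#'
#' Standard ROC area: the fraction of (active, inactive) pairs ranked in the
#' correct order. 1 when all actives precede all inactives, 0.5 on average
#' for a random ordering, 0 when all actives come last.
#'
#' @param r a `ranked_labels` (or a logical label vector).
#' @return numeric in \code{[0, 1]}.
#' @export
auc <- function(r) {
  r <- .as_ranked(r)
  # Mann-Whitney form: normalized by n (N - n) so the bounds are exactly 0/1
  1 - (sum(r$ranks) - r$n * (r$n + 1) / 2) / (r$n * (r$N - r$n))
}

#' Enrichment factor at a fraction of the ranked list
#'
#' Number of actives found among the top `chi` fraction, divided by the
#' count expected from a uniformly random ranking: EF(chi) =
#' sum_i \[r_i <= chi N\] / (chi n). Bounded by `min(1/chi, N/n)`.
#'
#' @param r a `ranked_labels`.
#' @param chi fraction of the list considered, 0 < chi < 1.
#' @return numeric fold enrichment.
#' @export
enrichment_factor <- function(r, chi) {
  r <- .as_ranked(r)
  stopifnot(is.numeric(chi), length(chi) == 1L, chi > 0, chi < 1)
  sum(r$ranks <= chi * r$N) / (chi * r$n)
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially rank-weighted enrichment: each active contributes
#' exp(-alpha r_i / N), normalized by the analytic random-ranking average
#' (n/N) (1 - exp(-alpha)) / (exp(alpha/N) - 1). Values near 1 indicate
#' random performance.
#'
#' @param r a `ranked_labels`.
#' @param alpha positive early-recognition parameter; 1/alpha plays the role
#'   of the EF fraction chi.
#' @param warn_condition warn when alpha n / N is not small (the regime where
#'   RIE saturates and comparisons across compositions degrade).
#' @return numeric.
#' @export
rie <- function(r, alpha, warn_condition = TRUE) {
  r <- .as_ranked(r)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  if (warn_condition && alpha * r$n / r$N > 1)
    warning(sprintf("alpha * n / N = %.2f is not << 1; RIE is near saturation",
                    alpha * r$n / r$N), call. = FALSE)
  num <- sum(exp(-alpha * r$ranks / r$N))
  denom <- (r$n / r$N) * (1 - exp(-alpha)) / (exp(alpha / r$N) - 1)
  num / denom
}

#' Minimum and maximum attainable RIE
#'
#' Closed-form bounds for a composition of `n` actives among `N` molecules:
#' RIE_min = (N/n) (1 - exp(alpha n / N)) / (1 - exp(alpha)),
#' RIE_max = (N/n) (1 - exp(-alpha n / N)) / (1 - exp(-alpha)).
#'
#' @param n number of actives.
#' @param N total number of molecules.
#' @param alpha positive weighting parameter.
#' @return named numeric vector `c(min =, max =)` with
#'   `min < 1 < max`.
#' @export
rie_bounds <- function(n, N, alpha) {
  stopifnot(n > 0, N > n, alpha > 0)
  ratio <- N / n
  c(min = ratio * (1 - exp(alpha * n / N)) / (1 - exp(alpha)),
    max = ratio * (1 - exp(-alpha * n / N)) / (1 - exp(-alpha)))
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' RIE rescaled by its attainable bounds so the score lies in \code{[0, 1]}:
#' (RIE - RIE_min) / (RIE_max - RIE_min). 1 for the perfect ranking, 0 for
#' the worst; depends on the ordering only.
#'
#' @inheritParams rie
#' @return numeric in \code{[0, 1]}.
#' @export
bedroc <- function(r, alpha) {
  r <- .as_ranked(r)
  b <- rie_bounds(r$n, r$N, alpha)
  (rie(r, alpha, warn_condition = FALSE) - b[["min"]]) /
    (b[["max"]] - b[["min"]])
}

## ---- metric specifications ------------------------------------------------

#' Construct a metric specification
#'
#' @param name one of `"AUC"`, `"EF"`, `"RIE"`, `"BEDROC"`.
#' @param parameter the EF fraction chi (0 < chi < 1) or the RIE/BEDROC
#'   alpha (> 0); `NULL` for AUC.
#' @return object of class `metric_spec` with a display `label` such as
#'   `"EF(0.05)"`.
#' @export
metric_spec <- function(name, parameter = NULL) {
  name <- match.arg(name, c("AUC", "EF", "RIE", "BEDROC"))
  if (name == "AUC") {
    if (!is.null(parameter)) stop("AUC takes no parameter", call. = FALSE)
  } else if (name == "EF") {
    stopifnot(is.numeric(parameter), parameter > 0, parameter < 1)
  } else {
    stopifnot(is.numeric(parameter), parameter > 0)
  }
  label <- if (is.null(parameter)) name else
    sprintf("%s(%g)", name, parameter)
  structure(list(name = name, parameter = parameter, label = label),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("<metric_spec>", x$label, "\n"); invisible(x)
}

#' Evaluate one metric on one ranked list
#' @param spec a `metric_spec`.
#' @param r a `ranked_labels`.
#' @return numeric score.
#' @export
evaluate_metric <- function(spec, r) {
  stopifnot(inherits(spec, "metric_spec"))
  switch(spec$name,
    AUC = auc(r),
    EF = enrichment_factor(r, spec$parameter),
    RIE = rie(r, spec$parameter, warn_condition = FALSE),
    BEDROC = bedroc(r, spec$parameter))
}

#' Read an evaluation-methods configuration file
#'
#' One method per line: a name optionally followed by its parameter,
#' e.g. `"AUC"`, `"EF 0.05"`, `"BEDROC 20"`. `#` comments and blank lines
#' are ignored.
#'
#' @param path file path.
#' @return list of `metric_spec`.
#' @export
load_metric_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("methods config '", path,
                                "' names no evaluation methods", call. = FALSE)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) == 1L) metric_spec(parts[1])
    else metric_spec(parts[1], as.numeric(parts[2]))
  })
}

## ---- per-repetition evaluation and ranking --------------------------------

#' Evaluate metrics over ranked screening results and rank fingerprints
#'
#' Stage 2 of the pipeline. For every (target, method, fingerprint,
#' repetition) the metric value is computed, and within each (target, method,
#' repetition) the fingerprints are ranked (rank 1 = best score, average
#' ranks on ties).
#'
#' @param results list of `ranked_screen_result` objects (see
#'   [score_target()]), covering every repetition of every fingerprint.
#' @param methods list of `metric_spec`.
#' @return data.frame with columns `target`, `method`, `fingerprint`,
#'   `repetition`, `value`, `rank`.
#' @export
evaluate <- function(results, methods) {
  stopifnot(length(results) > 0L, length(methods) > 0L)
  rows <- lapply(results, function(res) {
    stopifnot(inherits(res, "ranked_screen_result"))
    r <- ranked_labels(res$is_active)
    data.frame(
      target = res$target_id, fingerprint = res$fingerprint,
      repetition = res$repetition,
      method = vapply(methods, `[[`, "", "label"),
      value = vapply(methods, evaluate_metric, numeric(1), r = r),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # completeness: every fingerprint must have every repetition per target
  chk <- table(df$target, df$fingerprint, df$method)
  if (length(unique(as.vector(chk))) > 1L) {
    bad <- which(chk != max(chk), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete results: target %s, fingerprint %s, method %s",
                 dimnames(chk)[[1]][bad[1]], dimnames(chk)[[2]][bad[2]],
                 dimnames(chk)[[3]][bad[3]]), call. = FALSE)
  }
  # rank fingerprints within (target, method, repetition); higher value = better
  df$rank <- stats::ave(df$value,
                        df$target, df$method, df$repetition,
                        FUN = function(v) rank(-v, ties.method = "average"))
  rownames(df) <- NULL
  df
}
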