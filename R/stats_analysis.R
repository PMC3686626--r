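## Stage 3 (analysis): averaging, fingerprint ranking across targets, global
## and post-hoc pairwise Friedman tests with bootstrap maxT adjustment, and
## linear-regression correlation summaries.

#' Per-target average performance table
#'
#' Arithmetic mean of the metric values over repetitions, for every
#' (target, method, fingerprint) cell.
#'
#' @param values data.frame from [evaluate()].
#' @return data.frame with columns `target`, `method`, `fingerprint`,
#'   `mean_value`.
#' @export
average_performance <- function(values) {
  stopifnot(all(c("target", "method", "fingerprint", "value") %in%
                  names(values)))
  agg <- stats::aggregate(value ~ target + method + fingerprint, data = values,
                          FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg[order(agg$target, agg$method, agg$fingerprint), , drop = FALSE]
}

#' Build a rank matrix (target x repetition x fingerprint) for one method
#'
#' @param values data.frame from [evaluate()].
#' @param method method label (e.g. `"BEDROC(20)"`).
#' @return 3-d array `[target, repetition, fingerprint]` of within-repetition
#'   ranks, of class `rank_matrix`. Each (target, repetition) slice sums to
#'   k(k+1)/2 for k fingerprints.
#' @export
rank_matrix <- function(values, method) {
  v <- values[values$method == method, , drop = FALSE]
  if (nrow(v) == 0L) stop("no values for method '", method, "'", call. = FALSE)
  targets <- sort(unique(v$target))
  reps <- sort(unique(v$repetition))
  fps <- sort(unique(v$fingerprint))
  arr <- array(NA_real_, dim = c(length(targets), length(reps), length(fps)),
               dimnames = list(target = targets, repetition = reps,
                               fingerprint = fps))
  idx <- cbind(match(v$target, targets), match(v$repetition, reps),
               match(v$fingerprint, fps))
  arr[idx] <- v$rank
  if (anyNA(arr)) {
    bad <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf("missing rank for target %s, repetition %s, fingerprint %s",
                 targets[bad[1]], reps[bad[2]], fps[bad[3]]), call. = FALSE)
  }
  structure(arr, class = c("rank_matrix", "array"))
}

#' Per-target mean ranks over repetitions
#' @param rm a `rank_matrix`.
#' @return matrix target x fingerprint of mean ranks.
#' @export
target_mean_ranks <- function(rm) {
  apply(rm, c(1, 3), mean)
}

#' Average rank of each fingerprint across targets
#'
#' Mean of the per-target mean ranks; lower is better.
#'
#' @param rm a `rank_matrix`.
#' @return named numeric vector, one average rank per fingerprint, ordered by
#'   increasing average rank.
#' @export
average_rank <- function(rm) {
  sort(colMeans(target_mean_ranks(rm)))
}

## ---- Friedman machinery ---------------------------------------------------

# tie-corrected Friedman chi-square on a blocks x treatments matrix of
# observations (re-ranked within blocks)
.friedman_stat <- function(m) {
  b <- nrow(m); k <- ncol(m)
  rk <- t(apply(m, 1, rank, ties.method = "average"))
  if (k == 1L) stop("Friedman test needs >= 2 treatments", call. = FALSE)
  Rj <- colSums(rk)
  stat <- 12 / (b * k * (k + 1)) * sum(Rj^2) - 3 * b * (k + 1)
  # tie correction: divide by 1 - sum(t^3 - t) / (b (k^3 - k))
  tie <- sum(apply(rk, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie / (b * (k^3 - k))
  if (C <= 0) return(list(stat = 0, df = k - 1, p = 1))
  stat <- stat / C
  list(stat = stat, df = k - 1,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Global Friedman test across targets
#'
#' Tests for consistent differences between fingerprints, using targets as
#' blocks and the per-target mean ranks (over repetitions) as observations.
#' The tie-corrected chi-square statistic with k - 1 degrees of freedom is
#' used.
#'
#' @param rm a `rank_matrix` (or a target x fingerprint matrix of mean
#'   ranks).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman_global <- function(rm) {
  m <- if (inherits(rm, "rank_matrix")) target_mean_ranks(rm) else as.matrix(rm)
  if (ncol(m) < 2L) stop("need at least 2 fingerprints", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 targets", call. = FALSE)
  f <- .friedman_stat(m)
  list(statistic = f$stat, df = f$df, p_value = f$p)
}

## ---- post-hoc pairwise tests with bootstrap + maxT ------------------------

# one maxT pass: D is targets x pairs matrix of mean-rank differences.
# The pair statistic is T_i = |sum_t d_ti| / sqrt(sum_t d_ti^2) (studentized
# so pairs are on a common scale); the null distribution flips the sign of
# whole target rows (preserving the within-target correlation across pairs).
.maxt_adjust <- function(D, n_resamples, seed) {
  scale <- sqrt(colSums(D^2))
  scale[scale == 0] <- 1
  T_obs <- abs(colSums(D)) / scale
  S <- with_seed(seed, matrix(sample(c(-1, 1), n_resamples * nrow(D),
                                     replace = TRUE),
                              nrow = n_resamples))
  Tnull <- abs(S %*% D) / rep(scale, each = n_resamples)
  maxT <- apply(Tnull, 1, max)
  raw <- vapply(seq_along(T_obs), function(i)
    mean(Tnull[, i] >= T_obs[i] - 1e-12), numeric(1))
  adj <- vapply(T_obs, function(t) mean(maxT >= t - 1e-12), numeric(1))
  list(raw = raw, adjusted = pmax(adj, raw))
}

#' Post-hoc pairwise Friedman tests with bootstrap and maxT adjustment
#'
#' For each of `n_boot` bootstrap replicates, the repetition ranks of every
#' target are resampled with replacement (jointly across fingerprints, which
#' preserves the within-repetition correlation), per-target mean ranks are
#' recomputed, and all k(k-1)/2 pairwise comparisons are performed with
#' multiplicity adjustment by the resampling maxT scheme (null generated by
#' sign-flipping target rows, `n_adjust_resamples` resamples). Each pair thus
#' accumulates `n_boot` adjusted p-values, categorized against the
#' confidence level `alpha`:
#' `"-"` all below alpha (significant), `"X"` all above, `"o"` mixed.
#'
#' @param rm a `rank_matrix`.
#' @param alpha confidence level (default 0.05).
#' @param n_boot number of bootstrap replicates (default 100).
#' @param n_adjust_resamples sign-flip resamples inside the maxT step
#'   (default 1000).
#' @param seed integer master seed.
#' @param global_significant set `FALSE` to flag the reports as exploratory
#'   when the global test was not significant.
#' @return data.frame of class `pairwise_test_report` with one row per pair:
#'   `fp_a`, `fp_b`, `category`, `min_p`, `max_p`, `frac_below_alpha`, plus
#'   the full p-value matrix in `attr(, "adjusted_p")`
#'   (pairs x n_boot).
#' @export
posthoc_pairwise <- function(rm, alpha = 0.05, n_boot = 100L,
                             n_adjust_resamples = 1000L, seed = 1L,
                             global_significant = TRUE) {
  stopifnot(inherits(rm, "rank_matrix"))
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  dn <- dimnames(rm)
  fps <- dn$fingerprint
  k <- length(fps)
  if (k < 2L) stop("need at least 2 fingerprints", call. = FALSE)
  n_t <- dim(rm)[1]; n_r <- dim(rm)[2]
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  padj <- matrix(NA_real_, nrow = n_pairs, ncol = n_boot)
  for (b in seq_len(n_boot)) {
    boot_seed <- .sub_seed(seed, "boot", b, stage = 1L)
    res_idx <- with_seed(boot_seed,
                         matrix(sample.int(n_r, n_t * n_r, replace = TRUE),
                                nrow = n_t))
    M <- matrix(0, n_t, k)
    for (t in seq_len(n_t))
      M[t, ] <- apply(rm[t, res_idx[t, ], , drop = FALSE], 3, mean)
    D <- M[, pairs[1, ], drop = FALSE] - M[, pairs[2, ], drop = FALSE]
    adj <- .maxt_adjust(D, n_adjust_resamples,
                        .sub_seed(seed, "maxt", b, stage = 2L))
    padj[, b] <- adj$adjusted
  }
  below <- padj < alpha
  category <- ifelse(rowSums(below) == n_boot, "-",
                     ifelse(rowSums(below) == 0L, "X", "o"))
  out <- data.frame(
    fp_a = fps[pairs[1, ]], fp_b = fps[pairs[2, ]],
    category = category,
    min_p = apply(padj, 1, min), max_p = apply(padj, 1, max),
    frac_below_alpha = rowMeans(below),
    stringsAsFactors = FALSE)
  attr(out, "adjusted_p") <- padj
  attr(out, "alpha") <- alpha
  attr(out, "exploratory") <- !isTRUE(global_significant)
  class(out) <- c("pairwise_test_report", "data.frame")
  out
}

#' Render the pairwise-test categories as a significance matrix
#'
#' Upper-triangular matrix of `"-"` / `"X"` / `"o"` calls with fingerprints
#' ordered by increasing average rank (low ranks are better).
#'
#' @param report a `pairwise_test_report`.
#' @param avg_rank optional named average-rank vector used to order rows.
#' @return character matrix.
#' @export
category_matrix <- function(report, avg_rank = NULL) {
  fps <- unique(c(report$fp_a, report$fp_b))
  if (!is.null(avg_rank)) fps <- names(sort(avg_rank[fps]))
  m <- matrix("", length(fps), length(fps), dimnames = list(fps, fps))
  for (i in seq_len(nrow(report))) {
    a <- report$fp_a[i]; b <- report$fp_b[i]
    if (match(a, fps) > match(b, fps)) { tmp <- a; a <- b; b <- tmp }
    m[a, b] <- report$category[i]
  }
  m
}

## ---- correlation summaries ------------------------------------------------

#' Ordinary least-squares regression summary
#'
#' Simple linear regression of `y` on `x` with the quantities reported for
#' method/fingerprint correlation tables: slope, intercept, correlation
#' coefficient r, coefficient of determination r squared, and the RMSE of
#' the residuals.
#'
#' @param x,y numeric vectors of per-target values (>= 3 points).
#' @return list with `slope`, `intercept`, `r`, `r_squared`, `rmse`, `n`.
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0)
    stop("zero variance in x: degenerate fit", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2,
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       n = length(x))
}

#' All pairwise regression summaries between methods or fingerprints
#'
#' For every unordered pair of columns of a per-target value table, computes
#' [regress()]; supports subset filtering of targets (e.g. excluding one
#' collection).
#'
#' @param values data.frame from [average_performance()].
#' @param axis `"methods"` (correlate methods at a fixed fingerprint) or
#'   `"fingerprints"` (correlate fingerprints at a fixed method).
#' @param fix the fixed fingerprint or method label.
#' @param targets optional subset of targets to include.
#' @return data.frame with one row per pair: `a`, `b`, `slope`, `intercept`,
#'   `r`, `r_squared`, `rmse`, `n`; m items yield m(m-1)/2 rows.
#' @export
correlation_matrix <- function(values, axis = c("methods", "fingerprints"),
                               fix, targets = NULL) {
  axis <- match.arg(axis)
  v <- values
  if (!is.null(targets)) v <- v[v$target %in% targets, , drop = FALSE]
  if (axis == "methods") {
    v <- v[v$fingerprint == fix, , drop = FALSE]
    item_col <- "method"
  } else {
    v <- v[v$method == fix, , drop = FALSE]
    item_col <- "fingerprint"
  }
  if (nrow(v) == 0L) stop("no values left after filtering", call. = FALSE)
  wide <- stats::reshape(
    v[, c("target", item_col, "mean_value")],
    idvar = "target", timevar = item_col, direction = "wide")
  items <- sub("^mean_value\\.", "", names(wide)[-1])
  mat <- as.matrix(wide[, -1, drop = FALSE])
  pairs <- utils::combn(length(items), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    s <- regress(mat[, i], mat[, j])
    data.frame(a = items[i], b = items[j], slope = s$slope,
               intercept = s$intercept, r = s$r, r_squared = s$r_squared,
               rmse = s$rmse, n = s$n, stringsAsFactors = FALSE)
  }))
}
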