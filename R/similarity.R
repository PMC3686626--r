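## Similarity measures on fingerprint vectors.
##
## With a = N_A (features of A), b = N_B, c = N_{A&B} (common features),
## d = common off-bits and m = bit-string length, the supported measures are:
##   Dice            2c / (a + b)
##   Tanimoto        c / (a + b - c)
##   Cosine          c / sqrt(a b)
##   Russel          c / m
##   Kulczynski      (c/2) (1/a + 1/b)
##   McConnaughey    (c (a + b) - a b) / (a b)
##   Manhattan       1 - (a + b - 2c) / m
##   RogotGoldberg   c / (a + b) + d / (2m - a - b)
## For count vectors the multiset generalization is used:
## c = sum_i min(A_i, B_i), a = sum_i A_i, b = sum_i B_i. Manhattan and
## Rogot-Goldberg need the off-bit count d and are therefore defined for
## bit strings only.

.similarity_measures <- c("Dice", "Tanimoto", "Cosine", "Russel",
                          "Kulczynski", "McConnaughey", "Manhattan",
                          "RogotGoldberg")
.off_bit_measures <- c("Manhattan", "RogotGoldberg")

#' Supported similarity measure names
#' @return character vector.
#' @export
similarity_measures <- function() .similarity_measures

# common-feature count and totals for a pair of fpvecs
.abc <- function(x, y) {
  if (x$kind == "bitstring") {
    c_ <- length(intersect(x$idx, y$idx))
    a <- length(x$idx); b <- length(y$idx)
  } else {
    common <- intersect(x$idx, y$idx)
    c_ <- if (length(common)) {
      sum(pmin(x$counts[match(common, x$idx)], y$counts[match(common, y$idx)]))
    } else 0
    a <- sum(x$counts); b <- sum(y$counts)
  }
  c(a = a, b = b, c = c_)
}

.sim_from_abc <- function(a, b, c_, m, measure) {
  if (a == 0 || b == 0) return(0)   # zero-vector convention
  switch(measure,
    Dice = 2 * c_ / (a + b),
    Tanimoto = c_ / (a + b - c_),
    Cosine = c_ / sqrt(a * b),
    Russel = c_ / m,
    Kulczynski = (c_ / 2) * (1 / a + 1 / b),
    McConnaughey = (c_ * (a + b) - a * b) / (a * b),
    Manhattan = 1 - (a + b - 2 * c_) / m,
    RogotGoldberg = {
      d <- m - (a + b - c_)
      first <- c_ / (a + b)
      second <- if (2 * m - a - b > 0) d / (2 * m - a - b) else 0
      first + second
    },
    stop("unknown similarity measure '", measure, "'", call. = FALSE)
  )
}

#' Similarity between two fingerprint vectors
#'
#' @param x,y `fpvec` objects of the same kind (and length, for bit strings).
#' @param measure measure name; see [similarity_measures()]. Default
#'   `"Dice"`.
#' @return numeric similarity. Dice, Tanimoto, Cosine, Russel lie in
#'   \code{[0, 1]}; McConnaughey in \code{[-1, 1]}. Measures using common
#'   off-bits (Manhattan, Rogot-Goldberg) are defined for bit strings only.
#' @details Molecules with no features (zero vectors) get similarity 0 to
#'   everything, with a warning, to avoid 0/0.
#' @export
similarity <- function(x, y, measure = "Dice") {
  stopifnot(inherits(x, "fpvec"), inherits(y, "fpvec"))
  measure <- match.arg(measure, .similarity_measures)
  if (x$kind != y$kind)
    stop("fingerprints have different kinds: ", x$kind, " vs ", y$kind,
         call. = FALSE)
  if (x$kind == "bitstring" && x$length != y$length)
    stop("bit strings have different lengths", call. = FALSE)
  if (measure %in% .off_bit_measures && x$kind != "bitstring")
    stop("measure '", measure,
         "' uses common off-bits and is undefined for count vectors",
         call. = FALSE)
  v <- .abc(x, y)
  if (v[["a"]] == 0 || v[["b"]] == 0)
    warning("zero-feature fingerprint: similarity defined as 0", call. = FALSE)
  .sim_from_abc(v[["a"]], v[["b"]], v[["c"]], x$length, measure)
}

#' Maximum similarity of test molecules to a query set (MAX fusion)
#'
#' Scores every test fingerprint by its highest similarity over the query
#' fingerprints, the MAX group-fusion rule.
#'
#' @param queries non-empty list of query `fpvec`s.
#' @param test list of test `fpvec`s (entries may be `NULL` for molecules
#'   excluded from scoring; they receive `NA`).
#' @param measure similarity measure name.
#' @return numeric vector, one score per test entry.
#' @export
bulk_max_similarity <- function(queries, test, measure = "Dice") {
  queries <- Filter(Negate(is.null), queries)
  if (length(queries) == 0L) stop("empty query set", call. = FALSE)
  measure <- match.arg(measure, .similarity_measures)
  if (length(queries) && measure %in% .off_bit_measures &&
      queries[[1]]$kind != "bitstring")
    stop("measure '", measure,
         "' uses common off-bits and is undefined for count vectors",
         call. = FALSE)
  m <- queries[[1]]$length
  # validated once above; inner loop skips per-pair checks for speed
  vapply(test, function(tf) {
    if (is.null(tf)) return(NA_real_)
    best <- -Inf
    for (qf in queries) {
      v <- .abc(qf, tf)
      s <- .sim_from_abc(v[["a"]], v[["b"]], v[["c"]], m, measure)
      if (s > best) best <- s
    }
    best
  }, numeric(1))
}
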