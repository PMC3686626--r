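# stage 3: averaging, ranking, Friedman machinery, correlations

# random rank matrix under an exchangeable null
null_rank_matrix <- function(n_t = 8, n_r = 10, k = 3, seed = 1) {
  arr <- array(NA_real_, c(n_t, n_r, k),
               dimnames = list(target = paste0("t", seq_len(n_t)),
                               repetition = seq_len(n_r) - 1L,
                               fingerprint = LETTERS[seq_len(k)]))
  with_seed(seed, {
    for (t in seq_len(n_t)) for (r in seq_len(n_r))
      arr[t, r, ] <- sample(k)
  })
  structure(arr, class = c("rank_matrix", "array"))
}

# rank matrix where fingerprint "A" always wins and the rest are shuffled
dominant_rank_matrix <- function(n_t = 12, n_r = 10, k = 3) {
  arr <- null_rank_matrix(n_t, n_r, k, seed = 99)
  with_seed(97, {
    for (t in seq_len(n_t)) for (r in seq_len(n_r))
      arr[t, r, ] <- c(1, 1 + sample(k - 1))
  })
  arr
}

test_that("average performance is the arithmetic mean over repetitions", {
  df <- expand.grid(target = "T1", method = "AUC",
                    fingerprint = c("A", "B"), repetition = 0:49,
                    stringsAsFactors = FALSE)
  df$value <- ifelse(df$fingerprint == "A", 0.7, df$repetition %% 2)
  avg <- average_performance(df)
  expect_equal(avg$mean_value[avg$fingerprint == "A"], 0.7)
  expect_equal(avg$mean_value[avg$fingerprint == "B"], 0.5)
  # independent oracle on random values
  set.seed(2)
  df$value <- runif(nrow(df))
  avg <- average_performance(df)
  want <- tapply(df$value, df$fingerprint, mean)
  expect_equal(avg$mean_value, as.vector(want[avg$fingerprint]))
})

test_that("rank matrices validate completeness and sum to k(k+1)/2", {
  df <- expand.grid(target = c("T1", "T2"), method = "AUC",
                    fingerprint = c("A", "B", "C"), repetition = 0:4,
                    stringsAsFactors = FALSE)
  set.seed(1); df$value <- runif(nrow(df))
  df$rank <- stats::ave(df$value, df$target, df$repetition,
                        FUN = function(v) rank(-v))
  rm_ <- rank_matrix(df, "AUC")
  expect_equal(dim(rm_), c(2, 5, 3))
  expect_true(all(apply(rm_, c(1, 2), sum) == 6))
  expect_error(rank_matrix(df[-1, ], "AUC"), "missing rank")
  expect_error(rank_matrix(df, "BEDROC(20)"), "no values")
})

test_that("average ranks reproduce the trivial and oracle cases", {
  rm_ <- null_rank_matrix(10, 8, 3, seed = 5)
  # brute-force oracle
  want <- sort(colMeans(apply(rm_, c(1, 3), mean)))
  expect_equal(average_rank(rm_), want)
  # one fingerprint ranked 1 everywhere
  dom <- dominant_rank_matrix(6, 4, 3)
  expect_equal(unname(average_rank(dom)["A"]), 1.0)
  expect_equal(names(average_rank(dom))[1], "A")
})

test_that("the global Friedman test matches stats::friedman.test on tie-free data", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(8 * 4), 8, 4)   # 8 targets x 4 fingerprints, no ties
    got <- friedman_global(m)
    want <- stats::friedman.test(m)
    expect_equal(got$statistic, unname(want$statistic))
    expect_equal(got$df, unname(want$parameter))
    expect_equal(got$p_value, unname(want$p.value))
  }
})

test_that("Friedman degenerate and planted cases behave as expected", {
  # identical mean ranks across targets: statistic 0, p = 1
  m <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  g <- friedman_global(m)
  expect_true(g$p_value < 0.05)   # constant order is maximal evidence
  m_tie <- matrix(2, 6, 3)        # all tied: no evidence
  g2 <- friedman_global(m_tie)
  expect_equal(g2$p_value, 1)
  expect_error(friedman_global(m[, 1, drop = FALSE]), "2 fingerprints")
  # one of 5 fingerprints best in all 20 targets
  set.seed(4)
  m3 <- t(replicate(20, c(1, sample(2:5))))
  expect_lt(friedman_global(m3)$p_value, 0.05)
})

test_that("maxT adjustment is monotone and order-preserving", {
  set.seed(12)
  D <- matrix(rnorm(10 * 6), 10, 6)
  D[, 1] <- D[, 1] + 2   # one strong pair
  adj <- fpbench:::.maxt_adjust(D, 500, seed = 7)
  expect_true(all(adj$adjusted >= adj$raw - 1e-12))
  expect_true(all(adj$adjusted >= 0 & adj$adjusted <= 1))
  # the max-statistic step preserves the ordering of raw p-values
  o <- order(adj$raw)
  expect_true(!is.unsorted(adj$adjusted[o]))
})

test_that("post-hoc categories separate planted dominance from the null", {
  dom <- dominant_rank_matrix(n_t = 14, n_r = 12, k = 3)
  rep_ <- posthoc_pairwise(dom, n_boot = 25, n_adjust_resamples = 400,
                           seed = 2)
  expect_s3_class(rep_, "pairwise_test_report")
  # A dominates B and C in every repetition of every target
  ab <- rep_$category[rep_$fp_a == "A"]
  expect_true(all(ab == "-"))
  # identical rank distributions: never significant
  nullm <- null_rank_matrix(10, 10, 2, seed = 31)
  rep0 <- posthoc_pairwise(nullm, n_boot = 15, n_adjust_resamples = 300,
                           seed = 3)
  expect_equal(rep0$category, "X")
  # categories partition and reports count k(k-1)/2
  expect_true(all(rep_$category %in% c("-", "X", "o")))
  expect_equal(nrow(rep_), 3L)
  expect_error(posthoc_pairwise(dom, n_boot = 1), "n_boot")
})

test_that("category matrices order fingerprints by average rank", {
  dom <- dominant_rank_matrix(10, 6, 3)
  rep_ <- posthoc_pairwise(dom, n_boot = 5, n_adjust_resamples = 100,
                           seed = 1)
  cm <- category_matrix(rep_, average_rank(dom))
  expect_equal(rownames(cm)[1], "A")
  expect_true(all(cm[lower.tri(cm)] == ""))
})

test_that("regression summaries match the closed-form least-squares solution", {
  # exact line
  s <- regress(1:10, 2 * (1:10) + 3)
  expect_equal(s$slope, 2); expect_equal(s$intercept, 3)
  expect_equal(s$r_squared, 1); expect_equal(s$rmse, 0, tolerance = 1e-10)
  # degenerate cases
  expect_error(regress(rep(1, 5), 1:5), "zero variance")
  s0 <- regress(1:5, rep(2, 5))
  expect_equal(s0$slope, 0); expect_equal(s0$r, 0)
  # closed-form oracle on random data
  set.seed(9)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  s <- regress(x, y)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(s$slope, beta, tolerance = 1e-10)
  expect_equal(s$intercept, alpha, tolerance = 1e-10)
  expect_equal(s$rmse, sqrt(mean((y - alpha - beta * x)^2)),
               tolerance = 1e-10)
  expect_equal(s$r_squared, s$r^2)
})

test_that("correlation matrices emit m(m-1)/2 pairs and honor target subsets", {
  methods <- sprintf("M%d", 1:7)
  df <- expand.grid(target = sprintf("T%02d", 1:6), method = methods,
                    fingerprint = c("ECFP4", "AP"), stringsAsFactors = FALSE)
  set.seed(13); df$mean_value <- runif(nrow(df))
  cm <- correlation_matrix(df, "methods", fix = "ECFP4")
  expect_equal(nrow(cm), 21L)
  cm2 <- correlation_matrix(df, "fingerprints", fix = "M1")
  expect_equal(nrow(cm2), 1L)
  sub <- correlation_matrix(df, "methods", fix = "ECFP4",
                            targets = sprintf("T%02d", 1:4))
  expect_true(all(sub$n == 4))
})
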