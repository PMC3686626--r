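# evaluation metrics: AUC, EF, RIE, BEDROC, and the rank assignment

labels_at <- function(ranks, N) {
  l <- rep(FALSE, N); l[ranks] <- TRUE; l
}

test_that("AUC matches the pair-counting oracle and its endpoints", {
  expect_equal(auc(labels_at(1:2, 4)), 1.0)
  expect_equal(auc(labels_at(3:4, 4)), 0.0)
  expect_equal(auc(labels_at(c(1, 3), 4)), 0.75)
  set.seed(3)
  for (i in 1:25) {
    N <- sample(4:40, 1); n <- sample(seq_len(N - 1), 1)
    l <- labels_at(sample.int(N, n), N)
    expect_equal(auc(l), auc_oracle(l))
  }
  expect_error(auc(rep(TRUE, 5)), "undefined")
  expect_error(auc(rep(FALSE, 5)), "undefined")
})

test_that("EF reproduces hand-enumerated values and its bound", {
  # all 100 actives on top of 10100 molecules
  perfect <- labels_at(1:100, 10100)
  expect_equal(enrichment_factor(perfect, 0.05), 20)
  expect_equal(enrichment_factor(perfect, 0.01), 100)
  # no active in the top fraction
  expect_equal(enrichment_factor(labels_at(90:99, 100), 0.05), 0)
  # N=10, n=3, actives at {1,4,7}, chi=0.3: one active in top 3
  expect_equal(enrichment_factor(labels_at(c(1, 4, 7), 10), 0.3),
               1 / (0.3 * 3))
  # bound: EF <= min(1/chi, N/n)
  set.seed(8)
  for (i in 1:20) {
    N <- sample(20:200, 1); n <- sample(2:10, 1); chi <- runif(1, 0.02, 0.5)
    l <- labels_at(sample.int(N, n), N)
    expect_lte(enrichment_factor(l, chi), min(1 / chi, N / n) + 1e-12)
  }
})

test_that("RIE attains its closed-form bounds at the extreme rankings", {
  b <- rie_bounds(100, 10000, 20)
  expect_equal(round(b[["max"]], 1), 18.1)
  expect_equal(round(rie_bounds(100, 10000, 100)[["max"]], 1), 63.2)
  expect_true(b[["min"]] < 1 && 1 < b[["max"]])
  # perfect / worst rankings hit the bounds
  perfect <- labels_at(1:100, 10000)
  worst <- labels_at(9901:10000, 10000)
  expect_equal(rie(perfect, 20), b[["max"]], tolerance = 1e-9)
  expect_equal(rie(worst, 20, warn_condition = FALSE), b[["min"]],
               tolerance = 1e-9)
  # vanishing weight: both bounds approach 1
  b0 <- rie_bounds(10, 100, 1e-8)
  expect_equal(unname(b0), c(1, 1), tolerance = 1e-6)
})

test_that("RIE warns when alpha n / N is large", {
  expect_warning(rie(labels_at(1:50, 100), 20), "saturation")
  expect_silent(rie(labels_at(1:2, 1000), 20))
})

test_that("BEDROC is the min-max rescaling of RIE with exact endpoints", {
  for (np in list(c(5, 100), c(30, 15030), c(100, 10100))) {
    for (alpha in c(20, 100)) {
      expect_equal(bedroc(labels_at(seq_len(np[1]), np[2]), alpha), 1.0,
                   tolerance = 1e-9)
      worst <- labels_at((np[2] - np[1] + 1):np[2], np[2])
      expect_equal(bedroc(worst, alpha), 0.0, tolerance = 1e-9)
    }
  }
  # exhaustive small instance: all C(8,2) = 28 placements
  combos <- utils::combn(8, 2)
  vals <- apply(combos, 2, function(r) bedroc(labels_at(r, 8), 5))
  expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
  expect_equal(which.max(vals), 1L)   # actives at ranks {1,2}
  # order-only dependence: rescaling similarities changes nothing because
  # BEDROC consumes ranks, not scores (labels identical -> value identical)
  expect_equal(bedroc(labels_at(c(2, 5), 10), 20),
               bedroc(labels_at(c(2, 5), 10), 20))
})

test_that("metric specs validate parameters and parse from config files", {
  expect_error(metric_spec("AUC", 0.5), "no parameter")
  expect_error(metric_spec("EF", 1.5))
  expect_error(metric_spec("BEDROC", -1))
  expect_equal(metric_spec("EF", 0.05)$label, "EF(0.05)")
  cfg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("AUC", "EF 0.05", "BEDROC 20", "# comment", "RIE 100"), cfg)
  specs <- load_metric_config(cfg)
  expect_equal(vapply(specs, `[[`, "", "label"),
               c("AUC", "EF(0.05)", "BEDROC(20)", "RIE(100)"))
})

test_that("evaluate ranks fingerprints within repetitions with average ties", {
  mk <- function(fp, auc_like) {
    # two repetitions of a 2-active / 4-molecule list, quality controlled by
    # whether actives lead or trail
    lapply(0:1, function(r) {
      labs <- if (auc_like) c(TRUE, TRUE, FALSE, FALSE)
              else c(FALSE, TRUE, FALSE, TRUE)
      result_from_labels(labs, target = "T1", fp = fp, rep = r)
    })
  }
  res <- c(mk("good", TRUE), mk("bad", FALSE))
  ev <- evaluate(res, list(metric_spec("AUC")))
  expect_equal(ev$rank[ev$fingerprint == "good"], c(1, 1))
  expect_equal(ev$rank[ev$fingerprint == "bad"], c(2, 2))
  # identical scores share the average rank
  res2 <- c(mk("fpA", TRUE), mk("fpB", TRUE))
  ev2 <- evaluate(res2, list(metric_spec("AUC")))
  expect_true(all(ev2$rank == 1.5))
  # k fingerprints: per-repetition ranks sum to k(k+1)/2
  k <- 14
  res3 <- unlist(lapply(seq_len(k), function(i) {
    lapply(0:2, function(r) {
      labs <- labels_at(sample.int(10, 3), 10)
      result_from_labels(labs, target = "T1", fp = sprintf("fp%02d", i),
                         rep = r)
    })
  }), recursive = FALSE)
  ev3 <- evaluate(res3, list(metric_spec("BEDROC", 20)))
  sums <- tapply(ev3$rank, ev3$repetition, sum)
  expect_true(all(sums == k * (k + 1) / 2))
})

test_that("evaluate reports incomplete inputs by name", {
  res <- list(
    result_from_labels(c(TRUE, FALSE, TRUE, FALSE), fp = "A", rep = 0),
    result_from_labels(c(TRUE, FALSE, TRUE, FALSE), fp = "A", rep = 1),
    result_from_labels(c(TRUE, FALSE, TRUE, FALSE), fp = "B", rep = 0))
  expect_error(evaluate(res, list(metric_spec("AUC"))), "incomplete")
})
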