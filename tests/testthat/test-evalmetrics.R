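# helper to expand confusion counts into decision/label vectors
expand_counts <- function(tn, fp, tp, fn, excl0 = 0, excl1 = 0) {
  list(
    decisions = c(rep("negative", tn), rep("positive", fp),
                  rep("positive", tp), rep("negative", fn),
                  rep("excluded", excl0 + excl1)),
    labels = c(rep(0, tn + fp), rep(1, tp + fn), rep(0, excl0), rep(1, excl1))
  )
}

test_that("confusion reproduces the published worked examples", {
  # threshold-40 narrative: 16 positives of which 15 true, groups 28 vs 39
  e <- expand_counts(tn = 27, fp = 1, tp = 15, fn = 24)
  r <- confusion(e$decisions, e$labels)
  expect_equal(round(r$specificity, 2), 0.96)
  expect_equal(round(r$sensitivity, 2), 0.38)
  # threshold-17.1, groups 28 vs 11: accuracy 32/39
  e2 <- expand_counts(tn = 26, fp = 2, tp = 6, fn = 5)
  r2 <- confusion(e2$decisions, e2$labels)
  expect_equal(r2$accuracy, 100 * 32 / 39)
  expect_equal(round(r2$accuracy, 2), 82.05)
})

test_that("perfect and degenerate classifiers behave", {
  e <- expand_counts(tn = 10, fp = 0, tp = 10, fn = 0)
  r <- confusion(e$decisions, e$labels)
  expect_equal(r$accuracy, 100)
  expect_equal(r$specificity, 1)
  expect_equal(r$sensitivity, 1)
  expect_error(confusion(rep("excluded", 5), rep(1, 5)),
               class = "pulsevar_empty_report")
  expect_error(confusion(c("positive", "maybe"), c(1, 0)),
               class = "pulsevar_invalid_parameter")
})

test_that("confusion counts match brute-force tallies on all short vectors", {
  # exhaustive over every decision/label vector of length <= 4 plus a seeded
  # sample of length 5-6 (the full length-6 grid is checked in acceptance)
  decs <- c("positive", "negative", "excluded")
  check_case <- function(d, l) {
    adopted <- d != "excluded"
    if (!any(adopted)) return(invisible())
    r <- confusion(d, l)
    expect_identical(r$tp, sum(d == "positive" & l == 1))
    expect_identical(r$fp, sum(d == "positive" & l == 0))
    expect_identical(r$tn, sum(d == "negative" & l == 0))
    expect_identical(r$fn, sum(d == "negative" & l == 1))
    expect_identical(r$n_excluded, sum(!adopted))
    expect_equal(r$adopted_proportion, 100 * mean(adopted))
  }
  for (n in 2:4) {
    dg <- as.matrix(expand.grid(rep(list(decs), n)))
    lg <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (i in seq_len(nrow(dg))) for (j in seq_len(nrow(lg))) {
      check_case(dg[i, ], lg[j, ])
    }
  }
  set.seed(1)
  for (k in 1:200) {
    n <- sample(5:6, 1)
    check_case(sample(decs, n, replace = TRUE), sample(0:1, n, replace = TRUE))
  }
})

test_that("binary_auc is the single-operating-point trapezoid", {
  expect_equal(binary_auc(1.00, 0.60), 0.80)
  expect_equal(binary_auc(0.54, 0.92), 0.73)
  expect_equal(binary_auc(1, 1), 1)
  expect_equal(binary_auc(0.5, 0.5), 0.5)
})

test_that("rank_auc matches exhaustive pair counting, ties counted half", {
  expect_equal(rank_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  set.seed(2)
  for (k in 1:100) {
    n <- sample(4:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:4, n, replace = TRUE)  # integer scores force ties
    expect_equal(rank_auc(scores, labels), oracle_auc(scores, labels))
  }
  set.seed(3)
  big <- rnorm(4000)
  expect_equal(rank_auc(big, sample(0:1, 4000, replace = TRUE)), 0.5,
               tolerance = 0.05)
  expect_error(rank_auc(1:5, rep(1, 5)), class = "pulsevar_undefined_auc")
})

test_that("rank_auc equals binary_auc after binarizing at the threshold", {
  set.seed(4)
  scores <- rlnorm(60, 0, 2)
  labels <- as.integer(scores * rlnorm(60, 0, 1) > 1)
  if (sum(labels) %in% c(0, 60)) labels[1:2] <- c(0L, 1L)
  thr <- 1
  dec <- classify_single(scores, thr)
  r <- confusion(dec, labels)
  expect_equal(rank_auc(as.integer(scores > thr), labels),
               binary_auc(r$sensitivity, r$specificity))
})

test_that("likelihood_ratio_positive matches the published values", {
  expect_equal(round(likelihood_ratio_positive(0.81, 0.54), 2), 1.76)
  expect_equal(likelihood_ratio_positive(0.45, 0.80), 2.25)
  expect_equal(likelihood_ratio_positive(0.5, 0.5), 1)
  expect_identical(likelihood_ratio_positive(0.9, 1), Inf)
})

test_that("adopted proportion reproduces the published arithmetic", {
  e <- expand_counts(tn = 16, fp = 2, tp = 24, fn = 2, excl0 = 10, excl1 = 13)
  r <- confusion(e$decisions, e$labels)                 # 44 adopted of 67
  expect_equal(round(adopted_proportion(r), 1), 65.7)
  expect_equal(round(100 - adopted_proportion(r), 2), 34.33)
  e2 <- expand_counts(tn = 15, fp = 1, tp = 8, fn = 1, excl0 = 12, excl1 = 2)
  r2 <- confusion(e2$decisions, e2$labels)              # 25 adopted of 39
  expect_equal(round(adopted_proportion(r2), 1), 64.1)
  expect_equal(round(100 - adopted_proportion(r2), 2), 35.90)
  # no band: everything adopted
  e3 <- expand_counts(tn = 5, fp = 0, tp = 5, fn = 0)
  expect_equal(adopted_proportion(confusion(e3$decisions, e3$labels)), 100)
})

test_that("metrics are invariant to subject ordering", {
  set.seed(5)
  e <- expand_counts(tn = 7, fp = 3, tp = 6, fn = 4, excl0 = 2, excl1 = 1)
  r0 <- confusion(e$decisions, e$labels)
  perm <- sample(length(e$decisions))
  r1 <- confusion(e$decisions[perm], e$labels[perm])
  expect_equal(unclass(r0), unclass(r1))
  sc <- rnorm(20); lb <- sample(0:1, 20, replace = TRUE)
  if (length(unique(lb)) == 2) {
    p <- sample(20)
    expect_equal(rank_auc(sc, lb), rank_auc(sc[p], lb[p]))
  }
})

test_that("report JSON serializes counts and metrics", {
  e <- expand_counts(tn = 3, fp = 1, tp = 4, fn = 2)
  js <- jsonlite::fromJSON(report_json(confusion(e$decisions, e$labels)))
  expect_equal(js$tp, 4)
  expect_equal(js$accuracy, 70)
})
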