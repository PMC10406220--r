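test_that("stratified folds balance classes and sizes", {
  y <- rep(c("HC", "ICAS"), each = 24)
  set.seed(1)
  folds <- make_folds(y, k = 10)
  sizes <- as.integer(table(folds))
  expect_setequal(sizes, c(5L, 4L))
  expect_equal(sort(sizes, decreasing = TRUE), c(rep(5L, 8), rep(4L, 2)))
  for (f in 1:10) {
    tab <- table(y[folds == f])
    expect_lte(abs(tab["HC"] - tab["ICAS"]), 1)
  }
  # leave-one-out and error cases
  expect_equal(sort(unique(make_folds(y, k = 48, seed = 2))), 1:48)
  expect_error(make_folds(y, k = 49), "exceeds")
})

test_that("cross-validation is out-of-fold pure and exact on separable data", {
  d <- separable_data(n = 30, gap = 10, seed = 3)
  set.seed(4)
  cv <- cross_validate(d$x, d$y, n_trees = 50)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auc, 1)
  expect_true(all(!is.na(cv$scores)))
  # a training split with a single class is refused
  y_sorted <- sort(d$y)
  folds_bad <- ifelse(y_sorted == 0, 1L, 2L)
  expect_error(cross_validate(d$x, y_sorted, folds = folds_bad, n_trees = 10),
               "single class")
})

test_that("null labels give chance-level AUC", {
  aucs <- sapply(1:12, function(s) {
    d <- noise_data(n = 32, p = 8, seed = 500 + s)
    set.seed(600 + s)
    cross_validate(d$x, d$y, n_trees = 40)$auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("AUC equals the Mann-Whitney concordance and is rank-invariant", {
  set.seed(5)
  for (i in 1:10) {
    y <- rep(c(0, 1), each = 12)
    scores <- round(runif(24), 2)  # ties on purpose
    r <- roc_curve(scores, y)
    u <- unname(wilcox.test(scores[y == 1], scores[y == 0],
                            exact = FALSE)$statistic)
    expect_equal(r$auc, u / 144, tolerance = 1e-12)
    expect_equal(r$auc, trapezoid_auc(scores, y), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(roc_curve(exp(3 * scores), y)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("the Youden point maximizes sensitivity + specificity - 1", {
  y <- c(1, 1, 0, 0)
  r <- roc_curve(c(0.9, 0.8, 0.1, 0.2), y)
  yo <- youden_optimal(r)
  expect_equal(yo$youden, 1)
  expect_equal(yo$sensitivity, 1)
  expect_equal(yo$specificity, 1)
  expect_gt(yo$threshold, 0.2); expect_lte(yo$threshold, 0.8)
  set.seed(6)
  r2 <- roc_curve(runif(30), rep(c(0, 1), 15))
  expect_gte(youden_optimal(r2)$youden, 0)
})

test_that("fast DeLong agrees with the naive O(n^2) oracle", {
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    y <- c(rep(1, n1), rep(0, n0))
    a <- round(rnorm(n1 + n0), 1)  # rounded to force ties
    b <- round(a + rnorm(n1 + n0), 1)
    fast <- delong_test(a, b, y)
    slow <- naive_delong(a, b, y)
    expect_equal(fast$auc_a, slow$auc_a, tolerance = 1e-12)
    expect_equal(fast$auc_b, slow$auc_b, tolerance = 1e-12)
    expect_equal(fast$var_diff, slow$var_diff, tolerance = 1e-10)
    expect_equal(fast$p, slow$p, tolerance = 1e-10)
  }
  # identical scores: no evidence of different AUCs
  y <- rep(c(1, 0), 10)
  s <- rnorm(20)
  d <- delong_test(s, s, y)
  expect_equal(d$z, 0)
  expect_equal(d$p, 1)
  expect_error(delong_test(s, s, rep(1, 20)), "both classes")
})

test_that("fast DeLong matches the reference implementation in pROC", {
  set.seed(8)
  y <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("VOI-definition comparison reports all three modes", {
  co <- study_cohort(seed = 9)
  cmp <- compare_voi_definitions(co, n_repetitions = 2, n_trees = 40,
                                 seed = 10)
  expect_equal(cmp$summary$mode, c("whole", "iwsa", "inside_only"))
  expect_equal(cmp$summary$n_features, c(48L, 96L, 48L))
  expect_equal(nrow(cmp$delong), 3L)
  expect_true(all(cmp$delong$p >= 0 & cmp$delong$p <= 1))
  expect_true(all(cmp$summary$auc_mean >= 0 & cmp$summary$auc_mean <= 1))
})

test_that("nested selection trains one model per size on inner rankings", {
  co <- study_cohort(seed = 11)
  ft <- assemble_features(co, "iwsa")
  set.seed(12)
  folds <- make_folds(ft$y, k = 4)
  nest <- nested_feature_selection_cv(ft, folds = folds, max_size = 12,
                                      inner_repetitions = 2, n_trees = 40)
  expect_equal(nrow(nest$per_size), 12L)
  expect_equal(ncol(nest$scores), 12L)
  expect_length(nest$selected, 4L)
  for (sel in nest$selected) {
    expect_lte(nrow(sel), 12L)
    cnt <- table(parse_feature_name(sel$feature)$parameter)
    expect_true(all(cnt <= 2))  # deduped inner candidates
  }
  expect_true(nest$best_size %in% 1:12)
  expect_true(all(!is.na(nest$scores)))
})

test_that("repeat_evaluation summarizes repetitions", {
  out <- repeat_evaluation(function(seed) c(metric = 1.5), n_repetitions = 4,
                           seed = 13)
  expect_equal(unname(out$mean["metric"]), 1.5)
  expect_equal(unname(out$sd["metric"]), 0)
  one <- repeat_evaluation(function(seed) c(m = seed), n_repetitions = 1,
                           seed = 14)
  expect_equal(nrow(one$runs), 1L)
})
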