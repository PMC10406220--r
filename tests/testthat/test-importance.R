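test_that("repetition-averaged importance is deterministic and ranked", {
  d <- separable_data(n = 24, p = 6, seed = 1)
  a <- repeated_importance(d$x, d$y, n_repetitions = 5, n_trees = 40, seed = 2)
  b <- repeated_importance(d$x, d$y, n_repetitions = 5, n_trees = 40, seed = 2)
  expect_identical(a, b)
  expect_setequal(a$rank, seq_len(6))
  expect_equal(a$feature[1], "f1")  # the informative feature ranks first
  expect_true(all(diff(a$mean) <= 0))
  expect_error(repeated_importance(d$x, d$y, n_repetitions = 0), "repetitions")
})

test_that("averaging across repetitions contracts the spread of mean scores", {
  d <- separable_data(n = 30, p = 6, gap = 1.5, seed = 3)
  batch_means <- function(R, seeds) {
    vapply(seeds, function(s) {
      imp <- repeated_importance(d$x, d$y, n_repetitions = R, n_trees = 40,
                                 seed = s)
      imp$mean[imp$feature == "f1"]
    }, numeric(1))
  }
  sd10 <- sd(batch_means(10, 101:108))
  sd40 <- sd(batch_means(40, 201:208))
  expect_lt(sd40, sd10)  # ~1/sqrt(R) contraction
})

test_that("recursive elimination drops 10% per round and keeps signal", {
  # all features informative enough: set returned unchanged
  set.seed(4)
  n <- 40; y <- rep(c(0L, 1L), n / 2)
  x <- sapply(1:3, function(j) rnorm(n) + 3 * y)
  colnames(x) <- paste0("s", 1:3)
  out <- recursive_feature_elimination(x, y, n_repetitions = 5, n_trees = 50,
                                       seed = 5)
  expect_setequal(out$feature, colnames(x))
  expect_equal(attr(out, "n_iterations"), 1L)

  # one informative + 19 noise: drop arithmetic is floor-based
  keep <- sapply(1:5, function(s) {
    set.seed(s)
    x2 <- cbind(inf = rnorm(n) + 3 * y,
                matrix(rnorm(19 * n), n, 19,
                       dimnames = list(NULL, paste0("z", 1:19))))
    out2 <- recursive_feature_elimination(x2, y, n_repetitions = 5,
                                          n_trees = 50, seed = 100 + s)
    "inf" %in% out2$feature
  })
  expect_gte(sum(keep), 4)
})

test_that("the elimination schedule follows max(1, floor(0.1 m))", {
  # 96 -> drop floor(9.6) = 9 -> 87, per the stated rule
  m <- 96
  drop1 <- max(1, floor(0.10 * m))
  expect_equal(drop1, 9)
  expect_equal(m - drop1, 87)
  # 5 features -> drops exactly 1
  expect_equal(max(1, floor(0.10 * 5)), 1)
})

test_that("per-parameter dedup keeps best VOI and best difference", {
  ranked <- data.frame(
    feature = c("TTP_WM_inside_diff", "TTP_GM_inside_diff",
                "CBF_GM_inside_diff"),
    mean = c(0.9, 0.5, 0.8), sd = 0, rank = 1:3,
    stringsAsFactors = FALSE)
  out <- per_parameter_dedup(ranked)
  expect_setequal(out$feature, c("TTP_WM_inside_diff", "CBF_GM_inside_diff"))
  expect_equal(out$feature[1], "TTP_WM_inside_diff")

  # keeps one hemispheric AND one difference feature per parameter
  ranked2 <- data.frame(
    feature = c("CVR_GM_inside_ipsi", "CVR_WM_inside_ipsi",
                "CVR_GM_inside_diff", "TTP_WM_inside_contra"),
    mean = c(0.7, 0.6, 0.4, 0.3), sd = 0, rank = 1:4,
    stringsAsFactors = FALSE)
  out2 <- per_parameter_dedup(ranked2)
  expect_setequal(out2$feature, c("CVR_GM_inside_ipsi", "CVR_GM_inside_diff",
                                  "TTP_WM_inside_contra"))

  # idempotence and the <=2-per-parameter bound on a real ranking
  co <- study_cohort(seed = 6)
  imp <- repeated_importance(assemble_features(co, "iwsa"),
                             n_repetitions = 2, n_trees = 50, seed = 7)
  dd <- per_parameter_dedup(imp)
  expect_identical(per_parameter_dedup(dd)$feature, dd$feature)
  cnt <- table(parse_feature_name(dd$feature)$parameter)
  expect_true(all(cnt <= 2))
  expect_error(per_parameter_dedup(data.frame(feature = "bogus", mean = 1)),
               "unparseable")
})

test_that("random-subset validation puts a label copy on top", {
  set.seed(8)
  n <- 40; y <- rep(c(0L, 1L), n / 2)
  x <- cbind(copy = as.numeric(y) + rnorm(n, sd = 0.05),
             matrix(rnorm(15 * n), n, 15,
                    dimnames = list(NULL, paste0("z", 1:15))))
  rsv <- random_subset_validation(x, y, subset_size = 4, n_subsets = 30,
                                  n_trees = 60, seed = 9)
  pf <- rsv$per_feature
  expect_lt(pf$mean_norm_rank[pf$feature == "copy"], 0.2)
  expect_true(all(pf$n_subsets > 0))
  expect_gt(rsv$spearman, 0)
  expect_error(random_subset_validation(x, y, subset_size = 99), "exceeds")
})

test_that("subset validation of pure noise has no strong rank structure", {
  # subset and full rankings share the data set, so chance associations of
  # noise features with the fixed labels induce some agreement; it must stay
  # well below perfect and the rank distribution must stay near-uniform
  d <- noise_data(n = 30, p = 12, seed = 10)
  rsv <- random_subset_validation(d$x, d$y, subset_size = 4, n_subsets = 40,
                                  n_trees = 40, seed = 11)
  expect_lt(abs(rsv$spearman), 0.85)
  expect_lt(abs(mean(rsv$per_feature$mean_norm_rank) - 0.5), 0.15)
})

test_that("pure-noise importance is small with a mild negative bias", {
  # With no informative feature at all, out-of-bag sets are the sampling
  # complement of the in-bag data a tree overfits, so permuting a used noise
  # feature tends to move the tree's OOB error toward chance from above:
  # the null importance mean sits slightly below zero, never far from it.
  d <- noise_data(n = 30, p = 10, seed = 12)
  means <- vapply(1:40, function(r) {
    f <- fit_forest(d$x, d$y, n_trees = 60, seed = 30000 + r)
    mean(permutation_importance(f, seed = 40000 + r))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.5)
  expect_lte(mean(means), 0.05)
})
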