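test_that("feature assembly yields the canonical column structure", {
  co <- simulate_cohort(the_table, cohort_config(seed = 1))
  fi <- assemble_features(co, "iwsa")
  fw <- assemble_features(co, "whole")
  fo <- assemble_features(co, "inside_only")
  expect_equal(ncol(fi$x), 96L)
  expect_equal(ncol(fw$x), 48L)
  expect_equal(ncol(fo$x), 48L)
  info <- parse_feature_name(colnames(fi$x))
  expect_equal(unname(table(info$parameter)[mri_parameters()]),
               rep(12L, 8L), ignore_attr = TRUE)
  expect_error(assemble_features(co, "bogus"))
})

test_that("differences are ipsi minus contra and missing propagates", {
  voi <- setNames(rep(1, 64), carotidrf:::voi_slot_names())
  voi["TTP_WM_inside_ipsi"] <- 12.3
  voi["TTP_WM_inside_contra"] <- 11.7
  row <- assemble_features(voi, "iwsa")
  expect_equal(unname(row["TTP_WM_inside_diff"]), 0.6)
  voi["TTP_WM_inside_contra"] <- NA
  row <- assemble_features(voi, "iwsa")
  expect_true(is.na(row["TTP_WM_inside_diff"]))
  expect_true(is.na(row["TTP_WM_inside_contra"]))
  expect_false(is.na(row["TTP_WM_inside_ipsi"]))
})

test_that("whole-tissue features average the zone VOIs", {
  voi <- setNames(runif(64), carotidrf:::voi_slot_names())
  row <- assemble_features(voi, "whole")
  expect_equal(unname(row["CBF_GM_whole_ipsi"]),
               unname((voi["CBF_GM_inside_ipsi"] +
                         voi["CBF_GM_outside_ipsi"]) / 2))
})

test_that("hemisphere relabeling negates differences and swaps twins", {
  co <- simulate_cohort(the_table, cohort_config(seed = 5))
  swapped <- co
  nm <- colnames(co$voi)
  nm2 <- sub("_ipsi$", "_TMP", nm)
  nm2 <- sub("_contra$", "_ipsi", nm2)
  nm2 <- sub("_TMP$", "_contra", nm2)
  colnames(swapped$voi) <- nm2
  a <- assemble_features(co, "iwsa")$x
  b <- assemble_features(swapped, "iwsa")$x
  diffs <- grepl("_diff$", colnames(a))
  expect_equal(b[, diffs], -a[, diffs])
  expect_equal(b[, "CBF_GM_inside_ipsi"], a[, "CBF_GM_inside_contra"])
})

test_that("clinical screening appends only significant candidates", {
  co <- simulate_cohort(the_table, cohort_config(seed = 1))
  ft <- assemble_features(co, "iwsa")
  none <- add_clinical_features(ft, co, alpha = 0)
  expect_equal(ncol(none$x), 96L)
  expect_length(none$clinical_added, 0L)
  ext <- add_clinical_features(ft, co)
  expect_true("n_medications" %in% ext$clinical_added)
  expect_equal(ncol(ext$x), 96L + length(ext$clinical_added))
})

test_that("null clinical distributions are rarely appended", {
  hits <- sapply(1:40, function(s) {
    co <- simulate_cohort(the_table, cohort_config(seed = 7000 + s))
    set.seed(s)  # overwrite candidates with group-independent noise
    co$clinical$systolic_bp <- rnorm(48)
    co$clinical$diastolic_bp <- rnorm(48)
    co$clinical$n_medications <- rnorm(48)
    ft <- assemble_features(co, "iwsa")
    length(add_clinical_features(ft, co)$clinical_added)
  })
  # each candidate is a 5%-level test; 40 seeds x 3 tests ~ 6 expected hits
  expect_lt(sum(hits), 15)
  expect_gt(mean(hits == 0), 0.6)
})

test_that("watershed segmentation follows the strict percentile rule", {
  vols <- simulate_volumes(group = "HC", noise_sd = 0, seed = 1)
  # constant map: nothing strictly exceeds the percentile
  const <- array(5, dim(vols$brain_mask))
  expect_equal(sum(segment_iwsa(const, vols$brain_mask, smoothing_fwhm = 0)), 0)
  # noiseless fixture, no smoothing: exact recovery of the ground truth
  seg <- segment_iwsa(vols$maps$TTP, vols$brain_mask, smoothing_fwhm = 0)
  expect_identical(seg, vols$iwsa_truth)
  # continuous noise: mask cardinality close to 10% of brain voxels
  set.seed(2)
  noise <- array(rnorm(length(const)), dim(const))
  m <- segment_iwsa(noise, vols$brain_mask, smoothing_fwhm = 0)
  frac <- sum(m) / sum(vols$brain_mask)
  expect_gte(frac, 0.095); expect_lte(frac, 0.105)
  expect_error(segment_iwsa(const, array(FALSE, dim(const)), 0), "empty")
})

test_that("segmentation of noisy maps still recovers the watershed", {
  vols <- simulate_volumes(group = "ICAS", noise_sd = 0.3, seed = 3)
  seg <- segment_iwsa(vols$maps$TTP, vols$brain_mask, smoothing_fwhm = 0)
  dice <- 2 * sum(seg & vols$iwsa_truth) / (sum(seg) + sum(vols$iwsa_truth))
  expect_gt(dice, 0.9)
  # smoothing blurs the thin watershed band on this coarse phantom; the
  # segmented region must still overlap the truth by a majority
  seg2 <- segment_iwsa(vols$maps$TTP, vols$brain_mask, smoothing_fwhm = 2)
  dice2 <- 2 * sum(seg2 & vols$iwsa_truth) / (sum(seg2) + sum(vols$iwsa_truth))
  expect_gt(dice2, 0.5)
})

test_that("tissue thresholding is strict and ties go to GM", {
  g <- array(0.71, c(2, 2, 2)); w <- array(0, c(2, 2, 2))
  m <- make_tissue_masks(g, w)
  expect_true(all(m$gm)); expect_false(any(m$wm))
  g[] <- 0.70
  m <- make_tissue_masks(g, w)
  expect_false(any(m$gm))  # strict inequality
  g[] <- 0.8; w[] <- 0.9
  m <- make_tissue_masks(g, w)
  expect_true(all(m$wm)); expect_false(any(m$gm))
  w[] <- 0.8  # exact tie above threshold -> GM
  m <- make_tissue_masks(g, w)
  expect_true(all(m$gm)); expect_false(any(m$wm))
  g[] <- 1.2
  expect_error(make_tissue_masks(g, w), "\\[0, 1\\]")
})

test_that("R2' and rOEF follow the mq-BOLD model", {
  t2s <- array(0.050, c(2, 2, 1)); t2 <- array(0.100, c(2, 2, 1))
  expect_equal(unclass(compute_r2prime(t2s, t2))[1], 10)
  expect_equal(unclass(compute_r2prime(t2, t2))[1], 0)
  t2s[] <- 0.025
  expect_equal(unclass(compute_r2prime(t2s, t2))[1], 30)
  t2s[1] <- -1
  r <- compute_r2prime(t2s, t2)
  expect_true(is.na(r[1])); expect_equal(attr(r, "n_invalid"), 1L)

  r2p <- array(10, c(2, 2, 1)); rcbv <- array(0.0315, c(2, 2, 1))
  roef <- compute_roef(r2p, rcbv)
  expect_equal(unclass(roef)[1], 10 / (317 * 0.0315), tolerance = 1e-12)
  r2p[] <- 0
  expect_equal(unclass(compute_roef(r2p, rcbv))[1], 0)
  rcbv[1] <- 0
  out <- compute_roef(r2p, rcbv)
  expect_true(is.na(out[1]))
  rcbv[] <- 3.15  # percent-scaled input
  expect_error(compute_roef(r2p, rcbv), "percent")
})

test_that("VOI means are unweighted in-mask averages", {
  m <- array(7, c(4, 4, 2))
  masks <- list(a = array(c(TRUE, FALSE), c(4, 4, 2)),
                b = array(FALSE, c(4, 4, 2)))
  mu <- extract_voi_means(m, masks)
  expect_equal(unname(mu["a"]), 7)
  expect_true(is.na(mu["b"]))
  m[1, 1, 1] <- NaN  # non-finite voxels are dropped, not propagated
  expect_equal(unname(extract_voi_means(m, masks)["a"]), 7)
  expect_error(extract_voi_means(array(0, c(2, 2, 2)), masks), "mismatch")
})

test_that("VOI masks partition each tissue and whole means are consistent", {
  vols <- simulate_volumes(group = "ICAS", noise_sd = 0.2, seed = 4)
  tm <- make_tissue_masks(vols$gm_prob, vols$wm_prob)
  masks <- make_voi_masks(tm$gm, tm$wm, vols$iwsa_truth)
  # pairwise disjoint and inside/outside partitions the tissue-hemisphere
  nm <- names(masks)
  for (i in seq_along(masks))
    for (j in seq_len(i - 1L))
      expect_equal(sum(masks[[i]] & masks[[j]]), 0L)
  gm_ipsi <- masks$GM_inside_ipsi | masks$GM_outside_ipsi
  n_in <- sum(masks$GM_inside_ipsi); n_out <- sum(masks$GM_outside_ipsi)
  expect_equal(n_in + n_out, sum(gm_ipsi))
  map <- vols$maps$CBF
  whole_mean <- mean(map[gm_ipsi])
  mu <- extract_voi_means(map, masks)
  expect_equal(whole_mean,
               (n_in * mu["GM_inside_ipsi"] + n_out * mu["GM_outside_ipsi"]) /
                 (n_in + n_out), ignore_attr = TRUE)
})

test_that("map-mode extraction reproduces the fixture cell values", {
  vols <- simulate_volumes(group = "HC", noise_sd = 0, seed = 5)
  feats <- extract_features_from_maps(vols)
  expect_named(feats, carotidrf:::voi_slot_names(), ignore.order = FALSE)
  p <- the_table$parameters
  cell <- function(par, tis, zon, hem)
    p$mean[p$parameter == par & p$tissue == tis & p$zone == zon &
             p$hemisphere == hem & p$group == "HC"]
  # outside-zone cells are untouched by the TTP elevation: exact recovery
  expect_equal(unname(feats["CBF_GM_outside_ipsi"]),
               cell("CBF", "GM", "outside", "ipsi"), tolerance = 1e-10)
  expect_equal(unname(feats["OEF_WM_outside_contra"]),
               cell("OEF", "WM", "outside", "contra"), tolerance = 1e-8)
  expect_equal(unname(feats["TTP_WM_inside_ipsi"]),
               cell("TTP", "WM", "inside", "ipsi") + 2.0, tolerance = 1e-10)
})

test_that("rOEF stays in the plausible band on the noisy fixture", {
  vols <- simulate_volumes(group = "ICAS", noise_sd = 0.3, seed = 6)
  r2p <- compute_r2prime(vols$t2star, vols$t2)
  roef <- compute_roef(r2p, vols$maps$CBV / 100)
  v <- roef[vols$brain_mask]
  v <- v[is.finite(v)]
  expect_gt(mean(v >= 0 & v <= 2), 0.99)
})
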