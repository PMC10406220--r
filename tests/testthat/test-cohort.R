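test_that("degenerate noise reproduces the group means exactly", {
  cc <- cohort_config(n_icas = 4, n_hc = 4, rho_voi = 0, rho_hemi = 0,
                      severity_feature_shift = 0, seed = 1)
  co <- simulate_cohort(constant_table(), cc)
  mom_icas <- carotidrf:::.group_moments(the_table$parameters, "ICAS")
  mom_hc <- carotidrf:::.group_moments(the_table$parameters, "HC")
  for (i in which(co$group == "ICAS"))
    expect_equal(unname(co$voi[i, ]), mom_icas$mean)
  for (i in which(co$group == "HC"))
    expect_equal(unname(co$voi[i, ]), mom_hc$mean)
})

test_that("marginal means are calibrated at large n", {
  co <- simulate_cohort(the_table, cohort_config(n_icas = 10000, n_hc = 10000,
                                                 seed = 1))
  p <- the_table$parameters
  slots <- carotidrf:::voi_slots()
  for (grp in c("ICAS", "HC")) {
    v <- co$voi[co$group == grp, ]
    m <- carotidrf:::.group_moments(p, grp)
    # severity mixing inflates ICAS spread; use realized SE for the band
    se <- pmax(m$sd, apply(v, 2, sd)) / sqrt(nrow(v))
    z <- abs(colMeans(v) - m$mean) / se
    # 64 simultaneous 3-SE checks: allow the expected few boundary cases
    expect_gte(mean(z <= 3), 0.95)
    expect_true(all(z <= 4.5),
                info = paste(grp, "worst:", colnames(v)[which.max(z)]))
    if (grp == "HC") {
      zs <- abs(apply(v, 2, sd) - m$sd) / (m$sd / sqrt(2 * nrow(v)))
      expect_gte(mean(zs <= 3), 0.95)
      expect_true(all(zs <= 4.5))
    }
  }
})

test_that("marginal SDs are calibrated when the severity contrast is off", {
  co <- simulate_cohort(the_table,
                        cohort_config(n_icas = 8000, n_hc = 0,
                                      severity_feature_shift = 0, seed = 2))
  m <- carotidrf:::.group_moments(the_table$parameters, "ICAS")
  sds <- apply(co$voi, 2, sd)
  zs <- abs(sds - m$sd) / (m$sd / sqrt(2 * nrow(co$voi)))
  expect_gte(mean(zs <= 3), 0.95)  # 64 simultaneous checks
  expect_true(all(zs <= 4.5))
})

test_that("clinical generator hits subgroup fixtures and respects bounds", {
  co <- simulate_cohort(the_table,
                        cohort_config(n_icas = 10000, n_hc = 2000,
                                      severity_fraction = 1,
                                      n_missing_cognition = 0, seed = 3))
  cl <- co$clinical[co$group == "ICAS", ]
  expect_lt(abs(mean(cl$tmt_b) - 152.5), 3 * 66.9 / sqrt(nrow(cl)))
  expect_lt(abs(mean(cl$nascet) - 82.6), 3 * 8.3 / sqrt(nrow(cl)))
  expect_lt(abs(mean(cl$mmse) - 28.1), 3 * 2.0 / sqrt(nrow(cl)))
  expect_true(all(cl$mmse >= 0 & cl$mmse <= 30))
  expect_true(all(cl$tmt_a > 0 & cl$tmt_b > 0))
  expect_true(all(cl$nascet >= 70 & cl$nascet <= 99))
  expect_true(all(cl$n_medications %in% 0:3))
  hc <- co$clinical[co$group == "HC", ]
  expect_true(all(is.na(hc$nascet)))
  expect_lt(abs(mean(hc$systolic_bp) - 140.8), 3 * 21.5 / sqrt(nrow(hc)))
})

test_that("identical seeds give bit-identical cohorts", {
  a <- study_cohort(seed = 7)
  b <- study_cohort(seed = 7)
  expect_identical(a, b)
  c2 <- study_cohort(seed = 8)
  expect_false(identical(a$voi, c2$voi))
})

test_that("severity shift moves severe patients away from the HC centroid", {
  mom_hc <- carotidrf:::.group_moments(the_table$parameters, "HC")
  dist_severe <- function(shift) {
    co <- simulate_cohort(the_table,
                          cohort_config(n_icas = 2000, n_hc = 0,
                                        severity_feature_shift = shift,
                                        seed = 11))
    sev <- co$voi[co$clinical$severity == "severe", ]
    z <- sweep(sweep(sev, 2, mom_hc$mean, "-"), 2, mom_hc$sd, "/")
    mean(sqrt(rowSums(z^2)))
  }
  d <- vapply(c(0, 0.5, 1), dist_severe, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("missingness is map-level and exactly counted", {
  co <- study_cohort(seed = 21)
  slots <- carotidrf:::voi_slots()
  counts <- cohort_config()$missingness_counts
  miss_subj_par <- 0L
  for (p in mri_parameters()) {
    block <- co$voi[, slots$parameter == p, drop = FALSE]
    nmiss <- rowSums(is.na(block))
    expect_true(all(nmiss %in% c(0L, 8L)))  # all-or-none per parameter
    expect_equal(sum(nmiss == 8L), unname(counts[p]))
    miss_subj_par <- miss_subj_par + sum(nmiss == 8L)
  }
  expect_equal(miss_subj_par, 59L)
  expect_equal(round(100 * miss_subj_par / (48 * 8)), 15)
})

test_that("missingness edge cases behave", {
  co <- simulate_cohort(the_table, cohort_config(seed = 31))
  zero <- inject_missingness(co, counts = c(CBF = 0L), seed = 1)
  expect_identical(zero$voi, co$voi)
  sat <- inject_missingness(co, counts = c(CBF = 48L), seed = 1)
  slots <- carotidrf:::voi_slots()
  expect_true(all(is.na(sat$voi[, slots$parameter == "CBF"])))
  expect_false(anyNA(sat$voi[, slots$parameter != "CBF"]))
  expect_error(inject_missingness(co, counts = c(CBF = 49L)),
               "exceeds cohort size")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(rho_voi = 1), "correlations")
  expect_error(cohort_config(rho_hemi = -0.1), "correlations")
  expect_error(simulate_cohort(the_table, list()), "cohort_config")
})
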