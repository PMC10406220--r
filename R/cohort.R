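# Synthetic cohort generation calibrated to the group-statistics fixture.

#' Cohort simulation configuration
#'
#' Collects the knobs of the synthetic-cohort generator. The defaults encode
#' the study conditions: 24 patients and 24 age-matched controls, a binary
#' severity latent with 17/22 of patients severe, per-parameter map exclusion
#' counts, and block-equicorrelated VOI features.
#'
#' @param n_icas,n_hc Group sizes.
#' @param rho_voi Correlation between VOI means of the same parameter
#'   (different tissue/zone/hemisphere), in `[0, 1)`.
#' @param rho_hemi Correlation between hemispheric twins (same parameter,
#'   tissue and zone on the other hemisphere), in `[0, 1)`.
#' @param iwsa_effect_scale Multiplier concentrating the patient-vs-control
#'   mean shift inside individual watershed areas. Values above 1 scale the
#'   inside-iWSA group difference up and compensate the outside-iWSA
#'   difference down so the whole-tissue difference is unchanged; 1 leaves
#'   the fixture calibration untouched.
#' @param severity_fraction Fraction of patients in the severe subgroup.
#' @param severity_feature_shift Size of the severity contrast, as a multiple
#'   of each feature's standardized patient-vs-control group difference.
#'   Severe patients move this far beyond the patient mean away from the
#'   control centroid; mild patients are compensated toward it so the patient
#'   group marginals keep their calibrated means.
#' @param missingness_counts Named per-parameter subject counts for map-level
#'   exclusion, or `NULL` for [default_missingness_counts()].
#' @param n_missing_cognition Number of patients whose cognitive scores are
#'   missing (excluded from the cognition subanalysis).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_icas = 24L, n_hc = 24L, rho_voi = 0.5,
                          rho_hemi = 0.8, iwsa_effect_scale = 1.0,
                          severity_fraction = 17 / 22,
                          severity_feature_shift = 0.5,
                          missingness_counts = NULL,
                          n_missing_cognition = 2L, seed = NULL) {
  stopifnot(n_icas >= 0, n_hc >= 0, n_icas + n_hc >= 1)
  if (rho_voi < 0 || rho_voi >= 1 || rho_hemi < 0 || rho_hemi >= 1)
    stop("correlations must lie in [0, 1)")
  if (severity_fraction < 0 || severity_fraction > 1)
    stop("severity_fraction must lie in [0, 1]")
  if (is.null(missingness_counts))
    missingness_counts <- default_missingness_counts(n_icas + n_hc)
  if (any(missingness_counts > n_icas + n_hc))
    stop("missingness counts exceed cohort size")
  structure(list(n_icas = as.integer(n_icas), n_hc = as.integer(n_hc),
                 rho_voi = rho_voi, rho_hemi = rho_hemi,
                 iwsa_effect_scale = iwsa_effect_scale,
                 severity_fraction = severity_fraction,
                 severity_feature_shift = severity_feature_shift,
                 missingness_counts = missingness_counts,
                 n_missing_cognition = as.integer(n_missing_cognition),
                 seed = seed),
            class = "cohort_config")
}

# The 64 VOI slots in canonical order: parameter-major, then GM-inside,
# GM-outside, WM-inside, WM-outside, each as (ipsi, contra).
voi_slots <- function() {
  out <- expand.grid(hemisphere = .hemis, tz = seq_len(4L),
                     parameter = mri_parameters(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(parameter = out$parameter,
             tissue = .tissue_zone$tissue[out$tz],
             zone = .tissue_zone$zone[out$tz],
             hemisphere = out$hemisphere,
             stringsAsFactors = FALSE)
}

voi_slot_names <- function() {
  s <- voi_slots()
  paste(s$parameter, s$tissue, s$zone, s$hemisphere, sep = "_")
}

# Group mean/sd vectors over the 64 slots, in slot order.
.group_moments <- function(parameters, group) {
  s <- voi_slots()
  idx <- match(paste(s$parameter, s$tissue, s$zone, s$hemisphere, group),
               with(parameters,
                    paste(parameter, tissue, zone, hemisphere, group)))
  if (anyNA(idx)) stop("parameter table does not cover all 64 VOI slots")
  list(mean = parameters$mean[idx], sd = parameters$sd[idx])
}

# Block correlation over the 64 slots: rho_voi within a parameter, rho_hemi
# between hemispheric twins, independent across parameters.
.voi_correlation <- function(rho_voi, rho_hemi) {
  s <- voi_slots()
  n <- nrow(s)
  R <- diag(n)
  same_par <- outer(s$parameter, s$parameter, "==")
  twin <- same_par & outer(s$tissue, s$tissue, "==") &
    outer(s$zone, s$zone, "==") & outer(s$hemisphere, s$hemisphere, "!=")
  R[same_par & !diag(n)] <- rho_voi
  R[twin] <- rho_hemi
  R
}

# Truncated-normal sampler whose *sample mean* targets `mean`: the location
# of the underlying normal is moment-matched by root finding, then draws are
# taken by inverse-CDF so the RNG stream length is deterministic.
.rtruncnorm_matched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  if ((is.finite(lower) && mean <= lower) || (is.finite(upper) && mean >= upper))
    stop("target mean must lie strictly inside the truncation bounds")
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    z <- pnorm(b) - pnorm(a)
    e <- mu + sd * (dnorm(a) - dnorm(b)) / z
    if (!is.finite(e) || z < 1e-12) {
      # essentially all mass beyond a bound: mean collapses onto it
      e <- if (is.finite(upper) && pnorm(b) < 0.5) upper else lower
    }
    e
  }
  mu <- mean
  if (is.finite(lower) || is.finite(upper)) {
    mu <- uniroot(function(m) trunc_mean(m) - mean,
                  lower = mean - 10 * sd, upper = mean + 10 * sd,
                  tol = 1e-10)$root
  }
  a <- pnorm((lower - mu) / sd)
  b <- pnorm((upper - mu) / sd)
  mu + sd * qnorm(runif(n, a, b))
}

.draw_measure <- function(n, mean, sd, lower, upper) {
  .rtruncnorm_matched(n, mean, sd, lower, upper)
}

#' Simulate a synthetic ICAS/control cohort
#'
#' Draws per-subject VOI mean features from a multivariate normal whose
#' marginal means and SDs match the group parameter table, with
#' block-equicorrelation within parameters (`rho_voi`) and between
#' hemispheric twins (`rho_hemi`), plus clinical and cognitive covariates
#' from the clinical fixture. Patients carry a binary severity latent:
#' severe patients are shifted along the patient-vs-control mean-difference
#' direction away from controls, mild patients are compensated toward them,
#' so the patient-group feature means stay calibrated. Cognitive scores and
#' NASCET grade are drawn from the severity-subgroup fixtures; bounded scores
#' use truncated normals whose location is moment-matched so sample means
#' reproduce the fixture means.
#'
#' @param table Fixture from [load_default_parameter_table()].
#' @param config A [cohort_config()].
#' @return A list of class `icas_cohort` with elements `voi` (subjects x 64
#'   matrix of VOI means, `NA` = missing), `clinical` (data frame), `group`
#'   (factor `HC`/`ICAS`), `id`, and `config`.
#' @export
simulate_cohort <- function(table = load_default_parameter_table(),
                            config = cohort_config()) {
  if (!inherits(table, "icas_fixture")) stop("`table` must be an icas_fixture")
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config")
  if (!is.null(config$seed)) set.seed(config$seed)

  n_icas <- config$n_icas; n_hc <- config$n_hc
  n <- n_icas + n_hc
  group <- factor(rep(c("ICAS", "HC"), c(n_icas, n_hc)),
                  levels = c("HC", "ICAS"))

  icas <- .group_moments(table$parameters, "ICAS")
  hc <- .group_moments(table$parameters, "HC")

  # Concentrate the group difference inside iWSAs, zone-compensated so the
  # whole-tissue (inside+outside average) difference is preserved.
  sc <- config$iwsa_effect_scale
  if (sc != 1) {
    s <- voi_slots()
    delta <- icas$mean - hc$mean
    inside <- s$zone == "inside"
    partner <- match(paste(s$parameter, s$tissue, "inside", s$hemisphere),
                     paste(s$parameter, s$tissue, s$zone, s$hemisphere))
    adj <- delta
    adj[inside] <- sc * delta[inside]
    adj[!inside] <- delta[!inside] - (sc - 1) * delta[partner[!inside]]
    icas$mean <- hc$mean + adj
  }

  R <- .voi_correlation(config$rho_voi, config$rho_hemi)
  ch <- tryCatch(chol(R), error = function(e)
    stop("implied VOI correlation matrix is not positive definite ",
         "(rho_voi = ", config$rho_voi, ", rho_hemi = ", config$rho_hemi, ")"))

  draw_group <- function(m, mom) {
    z <- matrix(rnorm(m * 64L), m, 64L) %*% ch
    sweep(sweep(z, 2L, mom$sd, "*"), 2L, mom$mean, "+")
  }
  voi <- rbind(draw_group(n_icas, icas), draw_group(n_hc, hc))
  colnames(voi) <- voi_slot_names()

  # Severity latent: severe patients pushed away from the control centroid,
  # mild patients compensated so the realized patient mean is unchanged.
  severity <- rep("none", n)
  if (n_icas > 0) {
    n_severe <- round(config$severity_fraction * n_icas)
    sev_ids <- sample.int(n_icas, n_severe)
    severity[seq_len(n_icas)] <- "mild"
    severity[sev_ids] <- "severe"
    shift <- config$severity_feature_shift * (icas$mean - hc$mean)
    if (n_severe > 0 && config$severity_feature_shift != 0) {
      voi[sev_ids, ] <- sweep(voi[sev_ids, , drop = FALSE], 2L, shift, "+")
      mild_ids <- setdiff(seq_len(n_icas), sev_ids)
      if (length(mild_ids) > 0) {
        comp <- shift * n_severe / length(mild_ids)
        voi[mild_ids, ] <- sweep(voi[mild_ids, , drop = FALSE], 2L, comp, "-")
      }
    }
  }

  clinical <- .draw_clinical(table$clinical, group, severity, config)
  id <- sprintf("S%03d", seq_len(n))
  rownames(voi) <- id
  structure(list(voi = voi, clinical = clinical, group = group, id = id,
                 config = config),
            class = "icas_cohort")
}

.draw_clinical <- function(fix, group, severity, config) {
  n <- length(group)
  g <- fix$group
  sub <- fix$subgroup
  gv <- function(measure, col) g[[col]][g$measure == measure]
  sv <- function(measure, col) sub[[col]][sub$measure == measure]

  draw_group_measure <- function(measure) {
    out <- numeric(n)
    for (grp in c("ICAS", "HC")) {
      idx <- which(group == grp)
      pre <- if (grp == "ICAS") "icas" else "hc"
      out[idx] <- .draw_measure(length(idx),
                                gv(measure, paste0(pre, "_mean")),
                                gv(measure, paste0(pre, "_sd")),
                                gv(measure, "lower"), gv(measure, "upper"))
    }
    out
  }
  # Cognition and stenosis grade come from the severity subgroup fixtures
  # for patients; controls use the group fixture.
  draw_subgrouped <- function(measure, hc_too = TRUE) {
    out <- rep(NA_real_, n)
    for (sg in c("severe", "mild")) {
      idx <- which(severity == sg)
      pre <- sg
      out[idx] <- .draw_measure(length(idx),
                                sv(measure, paste0(pre, "_mean")),
                                sv(measure, paste0(pre, "_sd")),
                                sv(measure, "lower"), sv(measure, "upper"))
    }
    if (hc_too && measure %in% g$measure) {
      idx <- which(group == "HC")
      out[idx] <- .draw_measure(length(idx), gv(measure, "hc_mean"),
                                gv(measure, "hc_sd"),
                                gv(measure, "lower"), gv(measure, "upper"))
    }
    out
  }

  meds <- fix$medications
  med_draw <- sapply(seq_len(nrow(meds)), function(i) {
    prev <- ifelse(group == "ICAS", meds$icas_prev[i], meds$hc_prev[i])
    rbinom(n, 1L, prev)
  })
  colnames(med_draw) <- meds$drug

  side <- ifelse(runif(n) < fix$stenosis_right_prev, "right", "left")

  cl <- data.frame(
    age = draw_group_measure("age"),
    systolic_bp = draw_group_measure("systolic_bp"),
    diastolic_bp = draw_group_measure("diastolic_bp"),
    antiplatelet = med_draw[, "antiplatelet"],
    statin = med_draw[, "statin"],
    antihypertensive = med_draw[, "antihypertensive"],
    n_medications = rowSums(med_draw),
    nascet = draw_subgrouped("nascet", hc_too = FALSE),
    tmt_a = draw_subgrouped("tmt_a"),
    tmt_b = draw_subgrouped("tmt_b"),
    mmse = draw_subgrouped("mmse"),
    bdi = draw_group_measure("bdi"),
    stai = draw_group_measure("stai"),
    severity = severity,
    stenosis_side = ifelse(group == "ICAS", side, NA_character_),
    pseudo_ipsi_side = ifelse(group == "HC", side, NA_character_),
    stringsAsFactors = FALSE)

  # A few patients lack cognitive testing (excluded from the subanalysis).
  pat <- which(group == "ICAS")
  n_miss <- min(config$n_missing_cognition, length(pat))
  if (n_miss > 0) {
    miss <- sample(pat, n_miss)
    cl[miss, c("tmt_a", "tmt_b", "mmse", "bdi", "stai")] <- NA_real_
  }
  cl
}

#' Inject map-level missingness into a cohort
#'
#' For each parameter, marks all 8 VOI slots of that parameter missing for a
#' configured number of subjects drawn uniformly without replacement:
#' excluding a low-quality parameter map removes every VOI mean derived from
#' it, never a subset.
#'
#' @param cohort An `icas_cohort`.
#' @param counts Named per-parameter subject counts (default: the cohort
#'   config's counts).
#' @param seed Optional integer seed.
#' @return The cohort with `NA`s inserted in `voi`.
#' @export
inject_missingness <- function(cohort, counts = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "icas_cohort"))
  if (is.null(counts)) counts <- cohort$config$missingness_counts
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$voi)
  s <- voi_slots()
  for (p in names(counts)) {
    k <- counts[[p]]
    if (k > n) stop("missingness count for ", p, " exceeds cohort size")
    if (k == 0) next
    subj <- sample.int(n, k)
    cohort$voi[subj, s$parameter == p] <- NA_real_
  }
  cohort
}

#' @export
print.icas_cohort <- function(x, ...) {
  cat("Synthetic ICAS cohort:", sum(x$group == "ICAS"), "patients,",
      sum(x$group == "HC"), "controls\n")
  cat("VOI slots:", ncol(x$voi), " missing entries:",
      sum(is.na(x$voi)), sprintf("(%.1f%%)\n", 100 * mean(is.na(x$voi))))
  invisible(x)
}
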