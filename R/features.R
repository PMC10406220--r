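# Feature schema and feature-table assembly.

#' Canonical feature names
#'
#' Feature names serialize as `parameter_tissue_zone_side`, e.g.
#' `"TTP_WM_inside_diff"`. `zone` is `inside`/`outside` in iWSA mode,
#' `whole` in whole-brain mode; `side` is `ipsi`, `contra`, or `diff`
#' (the interhemispheric difference, defined as ipsi minus contra).
#'
#' @param mode One of `"iwsa"` (96 features), `"whole"` (48), or
#'   `"inside_only"` (48).
#' @return Character vector of feature names in canonical order
#'   (parameter-major; within a parameter: ipsi, contra, diff blocks over the
#'   fixed VOI order GM-inside, GM-outside, WM-inside, WM-outside).
#' @export
feature_names <- function(mode = c("iwsa", "whole", "inside_only")) {
  mode <- match.arg(mode)
  tz <- switch(mode,
    iwsa = .tissue_zone,
    whole = data.frame(tissue = c("GM", "WM"), zone = "whole",
                       stringsAsFactors = FALSE),
    inside_only = data.frame(tissue = c("GM", "WM"), zone = "inside",
                             stringsAsFactors = FALSE))
  out <- character(0)
  for (p in mri_parameters())
    for (side in c("ipsi", "contra", "diff"))
      out <- c(out, paste(p, tz$tissue, tz$zone, side, sep = "_"))
  out
}

#' @rdname feature_names
#' @param x Character vector of serialized feature names.
#' @return For `parse_feature_name()`, a data frame with columns `parameter`,
#'   `tissue`, `zone`, `side`, and `side_class` (`"hemispheric"` or
#'   `"difference"`).
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- lengths(parts) != 4L
  out <- data.frame(
    parameter = vapply(parts, function(p) p[1L][1], ""),
    tissue = vapply(parts, function(p) p[2L][1], ""),
    zone = vapply(parts, function(p) p[3L][1], ""),
    side = vapply(parts, function(p) p[4L][1], ""),
    stringsAsFactors = FALSE)
  bad <- bad | !(out$parameter %in% mri_parameters()) |
    !(out$tissue %in% .tissues) |
    !(out$zone %in% c("inside", "outside", "whole")) |
    !(out$side %in% c("ipsi", "contra", "diff"))
  if (any(bad))
    stop("unparseable feature name(s): ", paste(x[bad], collapse = ", "))
  out$side_class <- ifelse(out$side == "diff", "difference", "hemispheric")
  rownames(out) <- x
  out
}

#' Assemble the feature table of a cohort
#'
#' Turns per-subject VOI means into the named feature matrix of the requested
#' VOI definition: `iwsa` keeps inside/outside VOIs (8 hemispheric + 4
#' difference features per parameter, 96 in total), `whole` averages the
#' inside/outside VOI means into whole-tissue values (48 features), and
#' `inside_only` keeps only inside-iWSA VOIs (48 features). Interhemispheric
#' differences are ipsi minus contra and are missing if either side is
#' missing.
#'
#' @param cohort An `icas_cohort`, or a numeric vector of 64 named VOI means
#'   for a single subject.
#' @param mode VOI definition, see [feature_names()].
#' @return A list of class `icas_features`: `x` (subjects x features matrix),
#'   `y` (group factor), `id`, `mode`.
#' @export
assemble_features <- function(cohort, mode = c("iwsa", "whole", "inside_only")) {
  mode <- match.arg(mode)
  single <- !inherits(cohort, "icas_cohort")
  voi <- if (single) matrix(cohort, 1L, dimnames = list(NULL, names(cohort)))
         else cohort$voi
  if (is.null(colnames(voi)) || !setequal(colnames(voi), voi_slot_names()))
    stop("VOI means must carry the 64 canonical slot names")
  voi <- voi[, voi_slot_names(), drop = FALSE]

  hemi_value <- function(p, tissue, zone, hemi) {
    if (zone == "whole") {
      (voi[, paste(p, tissue, "inside", hemi, sep = "_")] +
         voi[, paste(p, tissue, "outside", hemi, sep = "_")]) / 2
    } else {
      voi[, paste(p, tissue, zone, hemi, sep = "_")]
    }
  }
  nm <- feature_names(mode)
  info <- parse_feature_name(nm)
  x <- matrix(NA_real_, nrow(voi), length(nm), dimnames = list(rownames(voi), nm))
  for (j in seq_along(nm)) {
    if (info$side[j] == "diff") {
      x[, j] <- hemi_value(info$parameter[j], info$tissue[j], info$zone[j], "ipsi") -
        hemi_value(info$parameter[j], info$tissue[j], info$zone[j], "contra")
    } else {
      x[, j] <- hemi_value(info$parameter[j], info$tissue[j], info$zone[j],
                           info$side[j])
    }
  }
  if (single) return(x[1L, ])
  structure(list(x = x, y = cohort$group, id = cohort$id, mode = mode),
            class = "icas_features")
}

#' Append significantly group-different clinical features
#'
#' Screens candidate clinical covariates with a two-sample test between
#' patients and controls (Welch t-test for continuous measures, Pearson
#' chi-squared for categorical ones) and appends those with `p <= alpha` to
#' the feature table. With the default candidates (systolic and diastolic
#' blood pressure, daily cerebrovascular medication count) and fixture-level
#' group differences this adds systolic blood pressure and the medication
#' count, extending a 96-feature table to 98 columns.
#'
#' @param features An `icas_features` table.
#' @param cohort The `icas_cohort` the table came from.
#' @param alpha Significance threshold for inclusion.
#' @param candidates Character vector of clinical columns to screen.
#' @param categorical Character vector naming which candidates are
#'   categorical.
#' @return The extended `icas_features`; appended columns are recorded in
#'   `$clinical_added`.
#' @export
add_clinical_features <- function(features, cohort, alpha = 0.05,
                                  candidates = c("systolic_bp", "diastolic_bp",
                                                 "n_medications"),
                                  categorical = character(0)) {
  stopifnot(inherits(features, "icas_features"),
            inherits(cohort, "icas_cohort"))
  added <- character(0)
  for (cand in candidates) {
    v <- cohort$clinical[[cand]]
    if (is.null(v)) stop("unknown clinical column: ", cand)
    p <- if (cand %in% categorical) {
      suppressWarnings(chisq.test(table(v, cohort$group))$p.value)
    } else {
      icas <- v[cohort$group == "ICAS"]; hc <- v[cohort$group == "HC"]
      if (sd(icas, na.rm = TRUE) == 0 && sd(hc, na.rm = TRUE) == 0) 1
      else t.test(icas, hc)$p.value
    }
    if (!is.na(p) && p <= alpha) added <- c(added, cand)
  }
  if (length(added) > 0) {
    extra <- as.matrix(cohort$clinical[, added, drop = FALSE])
    rownames(extra) <- rownames(features$x)
    features$x <- cbind(features$x, extra)
  }
  features$clinical_added <- added
  features
}

# Map-mode operations ---------------------------------------------------------

#' Segment individual watershed areas from a TTP map
#'
#' Smooths the time-to-peak map (Gaussian kernel, FWHM in voxel units along
#' each axis) and masks in-brain voxels whose smoothed value strictly exceeds
#' the 90th percentile of the smoothed in-brain distribution. The manual
#' editing of cortical watershed zones and vessel/ventricle exclusion applied
#' to real data is not part of this automatic rule.
#'
#' @param ttp 3-D array of TTP values (s).
#' @param brain_mask Logical array of the same shape.
#' @param smoothing_fwhm FWHM of the Gaussian smoothing kernel, in voxels
#'   (0 = no smoothing).
#' @param percentile Percentile defining the delay threshold.
#' @return Logical array: the watershed mask.
#' @export
segment_iwsa <- function(ttp, brain_mask, smoothing_fwhm = 4, percentile = 0.90) {
  if (!all(dim(ttp) == dim(brain_mask))) stop("grid mismatch")
  if (smoothing_fwhm < 0) stop("smoothing_fwhm must be >= 0")
  if (sum(brain_mask) == 0) stop("empty brain mask")
  sm <- if (smoothing_fwhm > 0) {
    masked_smooth(ttp, brain_mask, smoothing_fwhm)
  } else ttp
  vals <- sm[brain_mask]
  q <- quantile(vals, percentile, na.rm = TRUE, names = FALSE)
  out <- array(FALSE, dim(ttp))
  out[brain_mask] <- !is.na(vals) & vals > q
  out
}

# Mask-normalized separable Gaussian smoothing (keeps edges from being
# diluted by out-of-mask zeros).
masked_smooth <- function(vol, mask, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  v <- vol
  v[!mask] <- 0
  m <- array(as.numeric(mask), dim(mask))
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (o in seq_along(k)) {
      sh <- o - half - 1L
      idx_src <- .shift_index(dim(a)[axis], sh)
      perm <- switch(axis,
                     `1` = a[idx_src$src, , , drop = FALSE],
                     `2` = a[, idx_src$src, , drop = FALSE],
                     `3` = a[, , idx_src$src, drop = FALSE])
      switch(axis,
             `1` = {out[idx_src$dst, , ] <- out[idx_src$dst, , , drop = FALSE] + k[o] * perm},
             `2` = {out[, idx_src$dst, ] <- out[, idx_src$dst, , drop = FALSE] + k[o] * perm},
             `3` = {out[, , idx_src$dst] <- out[, , idx_src$dst, drop = FALSE] + k[o] * perm})
    }
    out
  }
  for (ax in 1:3) { v <- conv_axis(v, ax); m <- conv_axis(m, ax) }
  res <- vol
  res[mask] <- v[mask] / m[mask]
  res
}

.shift_index <- function(n, sh) {
  if (sh >= 0) list(src = seq_len(n - sh) + sh, dst = seq_len(n - sh))
  else list(src = seq_len(n + sh), dst = seq_len(n + sh) - sh)
}

#' Threshold tissue probability maps into GM/WM masks
#'
#' Voxels with probability strictly greater than `threshold` enter the tissue
#' mask; voxels passing both thresholds are assigned to the tissue with the
#' higher probability (ties to gray matter).
#'
#' @param gm_prob,wm_prob Arrays of tissue probabilities in `[0, 1]`.
#' @param threshold Probability cutoff (strict).
#' @return List with logical arrays `gm` and `wm`.
#' @export
make_tissue_masks <- function(gm_prob, wm_prob, threshold = 0.70) {
  if (!all(dim(gm_prob) == dim(wm_prob))) stop("grid mismatch")
  rng <- range(c(gm_prob, wm_prob), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("tissue probabilities must lie in [0, 1]")
  g <- !is.na(gm_prob) & gm_prob > threshold
  w <- !is.na(wm_prob) & wm_prob > threshold
  both <- g & w
  list(gm = g & (!both | gm_prob >= wm_prob),
       wm = w & (!both | wm_prob > gm_prob))
}

#' Reversible transverse relaxation rate R2'
#'
#' Voxelwise `R2' = 1/T2* - 1/T2` (inputs in seconds, output 1/s). Negative
#' values are retained; voxels with non-positive relaxation times are marked
#' invalid (`NA`) and counted in the `n_invalid` attribute.
#'
#' @param t2star_map,t2_map Arrays of relaxation times (s).
#' @return Array of R2' values (1/s) with attribute `n_invalid`.
#' @export
compute_r2prime <- function(t2star_map, t2_map) {
  if (!all(dim(t2star_map) == dim(t2_map))) stop("grid mismatch")
  bad <- (!is.na(t2star_map) & t2star_map <= 0) | (!is.na(t2_map) & t2_map <= 0)
  out <- 1 / t2star_map - 1 / t2_map
  out[bad] <- NA_real_
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Relative oxygen extraction fraction (mq-BOLD)
#'
#' Voxelwise `rOEF = R2' / (c * rCBV)` with the 3 T susceptibility constant
#' `c` (Hz). `rCBV` must be a fraction (percent values divided by 100); a
#' median above 0.5 is taken as percent-scaled input and rejected. Voxels
#' with non-positive `rCBV` are marked invalid rather than infinite.
#'
#' @param r2prime_map Array of R2' (1/s).
#' @param rcbv_map Array of relative cerebral blood volume as a fraction.
#' @param c Susceptibility scaling constant (Hz), default
#'   [mqbold_constant()].
#' @return Array of rOEF values with attribute `n_invalid`.
#' @export
compute_roef <- function(r2prime_map, rcbv_map, c = mqbold_constant()) {
  if (!all(dim(r2prime_map) == dim(rcbv_map))) stop("grid mismatch")
  if (c <= 0) stop("c must be positive")
  med <- stats::median(rcbv_map[!is.na(rcbv_map) & rcbv_map > 0])
  if (is.finite(med) && med > 0.5)
    stop("rCBV appears to be in percent; divide by 100 before calling")
  bad <- !is.na(rcbv_map) & rcbv_map <= 0
  out <- r2prime_map / (c * rcbv_map)
  out[bad] <- NA_real_
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Build the eight VOI masks of a subject
#'
#' Intersects GM/WM tissue masks with the watershed mask and a hemisphere
#' labeling into the 8 pairwise-disjoint VOIs (tissue x inside/outside x
#' hemisphere). Hemispheres are split at the midline of the first array axis
#' unless an explicit label array is given.
#'
#' @param gm_mask,wm_mask Logical tissue masks.
#' @param iwsa_mask Logical watershed mask.
#' @param ipsi_side `"left"` (low first-axis indices) or `"right"`, used by
#'   the midline rule.
#' @param hemi_labels Optional character array (`"ipsi"`/`"contra"`)
#'   overriding the midline split.
#' @return Named list of 8 logical arrays, names
#'   `tissue_zone_hemisphere` (e.g. `GM_inside_ipsi`).
#' @export
make_voi_masks <- function(gm_mask, wm_mask, iwsa_mask,
                           ipsi_side = "left", hemi_labels = NULL) {
  dm <- dim(gm_mask)
  if (!all(dm == dim(wm_mask)) || !all(dm == dim(iwsa_mask)))
    stop("grid mismatch")
  if (is.null(hemi_labels)) {
    half <- dm[1L] %/% 2L
    left <- slice.index(gm_mask, 1L) <= half
    ipsi <- if (ipsi_side == "left") left else !left
  } else {
    ipsi <- hemi_labels == "ipsi"
  }
  out <- list()
  for (tissue in .tissues) {
    tm <- if (tissue == "GM") gm_mask else wm_mask
    for (zone in .zones) {
      zm <- if (zone == "inside") iwsa_mask else !iwsa_mask
      for (hemi in .hemis) {
        hm <- if (hemi == "ipsi") ipsi else !ipsi
        out[[paste(tissue, zone, hemi, sep = "_")]] <- tm & zm & hm
      }
    }
  }
  out
}

#' Mean parameter value per VOI
#'
#' Arithmetic mean of finite in-mask voxels for each VOI mask; a VOI with no
#' valid voxel yields `NA`.
#'
#' @param param_map Array of parameter values.
#' @param voi_masks Named list of logical masks (see [make_voi_masks()]).
#' @return Named numeric vector of VOI means.
#' @export
extract_voi_means <- function(param_map, voi_masks) {
  vapply(voi_masks, function(m) {
    if (!all(dim(m) == dim(param_map))) stop("grid mismatch")
    v <- param_map[m]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Extract the canonical VOI means from simulated volumes
#'
#' Runs the map-mode pipeline on one subject's simulated volumes: watershed
#' segmentation from TTP, tissue thresholding, rOEF computation from
#' T2/T2*/rCBV, and per-VOI averaging — returning the 64 named VOI means
#' that [assemble_features()] accepts.
#'
#' @param vols An `icas_volumes` object from [simulate_volumes()].
#' @param smoothing_fwhm Passed to [segment_iwsa()].
#' @param tissue_threshold Passed to [make_tissue_masks()].
#' @return Named numeric vector of 64 VOI means.
#' @export
extract_features_from_maps <- function(vols, smoothing_fwhm = 0,
                                       tissue_threshold = 0.70) {
  stopifnot(inherits(vols, "icas_volumes"))
  iwsa <- segment_iwsa(vols$maps$TTP, vols$brain_mask, smoothing_fwhm)
  tm <- make_tissue_masks(vols$gm_prob, vols$wm_prob, tissue_threshold)
  masks <- make_voi_masks(tm$gm, tm$wm, iwsa, ipsi_side = vols$ipsi_side)
  r2p <- compute_r2prime(vols$t2star, vols$t2)
  roef <- compute_roef(r2p, vols$maps$CBV / 100)
  out <- numeric(0)
  for (p in mri_parameters()) {
    map <- if (p == "OEF") roef else vols$maps[[p]]
    mu <- extract_voi_means(map, masks)
    names(mu) <- paste(p, names(mu), sep = "_")
    out <- c(out, mu)
  }
  out[voi_slot_names()]
}
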