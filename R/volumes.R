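# Synthetic 3-D parameter maps for exercising the map-mode feature pipeline.

#' Simulate parameter maps, tissue probabilities and a brain mask
#'
#' Builds a small voxel phantom for one subject: an ellipsoidal brain with a
#' white-matter core and gray-matter shell, a designated watershed band at
#' the GM/WM interface holding a fixed fraction of brain voxels, and all
#' eight parameter maps whose voxel values follow the group fixture for the
#' voxel's (tissue, zone, hemisphere) cell — with TTP additionally elevated
#' inside the watershed band so delay-based segmentation can recover it.
#' T2 and T2* maps are emitted such that the mq-BOLD pipeline
#' (`compute_r2prime()` then `compute_roef()` with the CBV map as fraction)
#' reproduces the OEF map. Ground-truth watershed labels are returned for
#' segmentation tests.
#'
#' @param group `"ICAS"` or `"HC"`.
#' @param grid Integer vector of 3 dimensions.
#' @param ws_fraction Fraction of brain voxels in the watershed band,
#'   in (0, 1).
#' @param ttp_elevation Seconds added to TTP inside the watershed band.
#' @param noise_sd Voxel noise, as a multiple of each cell's fixture SD
#'   (0 = noiseless).
#' @param ipsi_side `"left"` or `"right"`.
#' @param table Fixture from [load_default_parameter_table()].
#' @param seed Optional integer seed.
#' @return A list of class `icas_volumes`: `maps` (named list of 8 arrays),
#'   `t2`, `t2star`, `gm_prob`, `wm_prob`, `brain_mask`, `iwsa_truth`,
#'   `ipsi_side`, `group`.
#' @export
simulate_volumes <- function(group = "ICAS", grid = c(32L, 32L, 16L),
                             ws_fraction = 0.10, ttp_elevation = 2.0,
                             noise_sd = 0.1, ipsi_side = "left",
                             table = load_default_parameter_table(),
                             seed = NULL) {
  if (ws_fraction <= 0 || ws_fraction >= 1)
    stop("ws_fraction must lie in (0, 1)")
  if (!group %in% c("ICAS", "HC")) stop("invalid group label: ", group)
  if (!is.null(seed)) set.seed(seed)

  cx <- (grid + 1) / 2
  ax <- grid / 2 - 0.5
  ix <- slice.index(array(0, grid), 1L)
  iy <- slice.index(array(0, grid), 2L)
  iz <- slice.index(array(0, grid), 3L)
  r <- sqrt(((ix - cx[1]) / ax[1])^2 + ((iy - cx[2]) / ax[2])^2 +
              ((iz - cx[3]) / ax[3])^2)
  brain <- r <= 1
  wm_core <- 0.7

  gm_prob <- array(0, grid); wm_prob <- array(0, grid)
  gm_prob[brain & r > wm_core] <- 0.9
  wm_prob[brain & r <= wm_core] <- 0.9
  gm_prob[brain & r <= wm_core] <- 0.05
  wm_prob[brain & r > wm_core] <- 0.05

  # Watershed band: the ws_fraction of brain voxels closest to the GM/WM
  # interface (deterministic tie-break by voxel index).
  n_ws <- round(ws_fraction * sum(brain))
  score <- abs(r - wm_core)
  ord <- order(score[brain])
  truth <- array(FALSE, grid)
  idx_brain <- which(brain)
  truth[idx_brain[ord[seq_len(n_ws)]]] <- TRUE

  half <- grid[1L] %/% 2L
  left <- ix <= half
  ipsi <- if (ipsi_side == "left") left else !left

  tissue <- ifelse(r <= wm_core, "WM", "GM")
  zone <- ifelse(truth, "inside", "outside")
  hemi <- ifelse(ipsi, "ipsi", "contra")

  params <- table$parameters[table$parameters$group == group, ]
  cell_key <- with(params, paste(parameter, tissue, zone, hemisphere))
  maps <- list()
  for (p in mri_parameters()) {
    key <- paste(p, tissue, zone, hemi)
    idx <- match(key, cell_key)
    vals <- params$mean[idx]
    if (noise_sd > 0)
      vals <- vals + rnorm(length(vals), sd = noise_sd * params$sd[idx])
    m <- array(vals, grid)
    m[!brain] <- NA_real_
    maps[[p]] <- m
  }
  maps$TTP[truth] <- maps$TTP[truth] + ttp_elevation

  # Invert the mq-BOLD model so the OEF map is recoverable from T2/T2*/CBV.
  t2 <- array(NA_real_, grid); t2[brain] <- 0.100
  rcbv_frac <- maps$CBV / 100
  r2p <- maps$OEF * mqbold_constant() * rcbv_frac
  t2star <- 1 / (r2p + 1 / t2)

  structure(list(maps = maps, t2 = t2, t2star = t2star, gm_prob = gm_prob,
                 wm_prob = wm_prob, brain_mask = brain, iwsa_truth = truth,
                 ipsi_side = ipsi_side, group = group),
            class = "icas_volumes")
}

#' Write simulated volumes as NIfTI-1 files with a JSON sidecar
#'
#' @param vols An `icas_volumes` object.
#' @param dir Output directory (created if needed).
#' @param subject Subject label used in file names.
#' @return Invisibly, the paths written.
#' @export
write_volumes <- function(vols, dir, subject = "S001") {
  stopifnot(inherits(vols, "icas_volumes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(arr, name) {
    path <- file.path(dir, paste0(subject, "_", name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    paths <<- c(paths, path)
  }
  for (p in names(vols$maps)) wr(vols$maps[[p]], p)
  wr(vols$t2, "T2"); wr(vols$t2star, "T2star")
  wr(vols$gm_prob, "GMprob"); wr(vols$wm_prob, "WMprob")
  wr(vols$brain_mask + 0, "brainmask"); wr(vols$iwsa_truth + 0, "iwsatruth")
  sidecar <- file.path(dir, paste0(subject, ".json"))
  jsonlite::write_json(list(subject = subject, group = vols$group,
                            ipsi_side = vols$ipsi_side,
                            parameters = names(vols$maps)),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, sidecar))
}
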