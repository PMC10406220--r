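# Repetition-averaged importance, recursive elimination, per-parameter
# deduplication and random-subset rank validation.

.derive_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Repetition-averaged permutation importance
#'
#' Fits `n_repetitions` independently seeded forests and averages the
#' per-feature OOB permutation-importance scores.
#'
#' @param x Feature matrix or `icas_features` table.
#' @param y Class labels (see [fit_forest()]).
#' @param n_repetitions Number of forests averaged.
#' @param n_trees,mtry,max_surrogates Forest parameters.
#' @param seed Master seed; every repetition derives its own seed from it.
#' @return A data frame of class `icas_importance`: `feature`, `mean`, `sd`
#'   (over repetitions), `rank`, ordered by decreasing mean score; attributes
#'   `n_repetitions` and `seed`.
#' @export
repeated_importance <- function(x, y = NULL, n_repetitions = 1000L,
                                n_trees = 300L, mtry = NULL,
                                max_surrogates = 5L, seed = NULL) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  seeds <- .derive_seeds(n_repetitions, seed)
  scores <- matrix(NA_real_, n_repetitions, ncol(x))
  for (r in seq_len(n_repetitions)) {
    set.seed(seeds[r])
    f <- fit_forest(x, y, n_trees = n_trees, mtry = mtry,
                    max_surrogates = max_surrogates)
    scores[r, ] <- permutation_importance(f)
  }
  mean_s <- colMeans(scores)
  sd_s <- if (n_repetitions > 1) apply(scores, 2L, sd) else rep(0, ncol(x))
  out <- data.frame(feature = colnames(x), mean = mean_s, sd = sd_s,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_repetitions") <- n_repetitions
  attr(out, "seed") <- seed
  class(out) <- c("icas_importance", "data.frame")
  out
}

#' Recursive feature elimination by importance score
#'
#' Repeatedly computes repetition-averaged importances on the current
#' feature set and drops the lowest-ranked `drop_fraction` of features
#' (at least one) until every surviving feature scores above `score_floor`.
#'
#' @inheritParams repeated_importance
#' @param drop_fraction Fraction of features dropped per iteration.
#' @param score_floor Importance score all survivors must exceed.
#' @param n_repetitions Importance repetitions per iteration (a reduced
#'   default relative to the final 1000-repetition averaging).
#' @return An `icas_importance` data frame of the surviving features with
#'   their final scores; attribute `n_iterations`.
#' @export
recursive_feature_elimination <- function(x, y = NULL, drop_fraction = 0.10,
                                          score_floor = 0.1,
                                          n_repetitions = 100L,
                                          n_trees = 300L, mtry = NULL,
                                          seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  seeds <- .derive_seeds(ncol(x) + 1L, seed)  # one per possible iteration
  keep <- colnames(x)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    imp <- repeated_importance(x[, keep, drop = FALSE], y,
                               n_repetitions = n_repetitions,
                               n_trees = n_trees, mtry = mtry,
                               seed = seeds[iter])
    if (min(imp$mean) > score_floor) break
    if (length(keep) == 1L) {
      warning("all features eliminated; returning the last survivor")
      break
    }
    n_drop <- max(1L, floor(drop_fraction * length(keep)))
    n_drop <- min(n_drop, length(keep) - 1L)
    keep <- imp$feature[seq_len(nrow(imp) - n_drop)]
  }
  attr(imp, "n_iterations") <- iter
  imp
}

#' Keep the best VOI and best VOI-difference feature per parameter
#'
#' From a ranked feature set, retains per MRI parameter at most one
#' hemispheric feature (sides ipsi/contra) and one interhemispheric
#' difference feature — whichever of each class scores highest — and
#' re-ranks the survivors by descending score.
#'
#' @param ranked An `icas_importance` data frame (or any data frame with
#'   `feature` and `mean` columns).
#' @return The deduplicated, re-ranked data frame.
#' @export
per_parameter_dedup <- function(ranked) {
  info <- parse_feature_name(ranked$feature)
  cls <- paste(info$parameter, info$side_class)
  ord <- order(-ranked$mean, ranked$feature)
  keep <- ord[!duplicated(cls[ord])]
  out <- ranked[sort(keep), , drop = FALSE]
  out <- out[order(-out$mean, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- class(ranked)
  out
}

#' Validate an importance ranking on random feature subsets
#'
#' Fits forests on random subsets of `subset_size` features and records each
#' feature's within-subset importance rank, normalized to (rank - 1) /
#' (subset_size - 1) so 0 is best. Reports the mean normalized rank per
#' feature across the subsets containing it and its Spearman correlation
#' with the full-set ranking.
#'
#' @inheritParams repeated_importance
#' @param subset_size Features per random subset.
#' @param n_subsets Number of subsets.
#' @param full_ranking Optional `icas_importance` from the full feature set;
#'   computed (with `n_repetitions` repetitions) when absent.
#' @return A list: `per_feature` (data frame `feature`, `mean_norm_rank`,
#'   `n_subsets`), `spearman` (correlation between subset-based and
#'   full-set orderings).
#' @export
random_subset_validation <- function(x, y = NULL, subset_size = 12L,
                                     n_subsets = 100L, n_repetitions = 1L,
                                     n_trees = 300L, full_ranking = NULL,
                                     seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  p <- ncol(x)
  if (subset_size > p) stop("subset_size exceeds the number of features")
  seeds <- .derive_seeds(n_subsets + 1L, seed)
  if (is.null(full_ranking))
    full_ranking <- repeated_importance(x, y, n_repetitions = n_repetitions,
                                        n_trees = n_trees,
                                        seed = seeds[n_subsets + 1L])
  rank_sum <- setNames(numeric(p), colnames(x))
  rank_n <- setNames(integer(p), colnames(x))
  for (s in seq_len(n_subsets)) {
    set.seed(seeds[s])
    cols <- sample.int(p, subset_size)
    f <- fit_forest(x[, cols, drop = FALSE], y, n_trees = n_trees)
    sc <- permutation_importance(f)
    rk <- rank(-sc, ties.method = "average")
    norm <- if (subset_size > 1) (rk - 1) / (subset_size - 1) else rep(0, 1)
    nm <- colnames(x)[cols]
    rank_sum[nm] <- rank_sum[nm] + norm
    rank_n[nm] <- rank_n[nm] + 1L
  }
  per_feature <- data.frame(
    feature = colnames(x),
    mean_norm_rank = ifelse(rank_n > 0, rank_sum / rank_n, NA_real_),
    n_subsets = rank_n, stringsAsFactors = FALSE)
  m <- match(full_ranking$feature, per_feature$feature)
  ok <- !is.na(per_feature$mean_norm_rank[m])
  spearman <- if (sum(ok) > 2)
    cor(-per_feature$mean_norm_rank[m][ok], full_ranking$mean[ok],
        method = "spearman")
  else NA_real_
  list(per_feature = per_feature, spearman = spearman)
}
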