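# Cross-validation, ROC metrics, VOI-definition comparison, nested feature
# selection and DeLong's test for correlated ROC curves.

#' Stratified fold assignment
#'
#' Randomly assigns subjects to `k` nearly equal folds, stratified so that
#' within each class the fold counts differ by at most one; the per-class
#' remainders are rotated across folds so overall fold sizes also differ by
#' at most one.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @param stratified Set `FALSE` for plain random assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k = 10L, seed = NULL, stratified = TRUE) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of subjects")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(n)
  if (!stratified) {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold <- sample(rep.int(seq_len(k), sizes))
    return(fold)
  }
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    m <- length(idx)
    sizes <- rep(m %/% k, k)
    r <- m %% k
    if (r > 0) {
      extras <- ((offset + seq_len(r) - 1L) %% k) + 1L
      sizes[extras] <- sizes[extras] + 1L
      offset <- offset + r
    }
    fold[idx[sample.int(m)]] <- rep.int(seq_len(k), sizes)
  }
  fold
}

# ROC machinery ---------------------------------------------------------------

#' ROC curve from vote scores
#'
#' Builds the ROC curve over all distinct score thresholds (prediction is
#' positive when score >= threshold) with trapezoidal AUC, which for tied
#' scores equals the Mann-Whitney concordance.
#'
#' @param scores Numeric vote fractions (higher = more patient-like).
#' @param labels Class labels (patient class = positive).
#' @return A list of class `icas_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- .as_class01(labels)
  if (anyNA(scores)) {
    keep <- !is.na(scores)
    scores <- scores[keep]; y <- y[keep]
  }
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  # trapezoid over (1 - spec, sens), ordered by decreasing threshold
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(c(0, fpr)) * (head(c(0, tpr), -1) + tpr) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "icas_roc")
}

#' Operating point at maximum Youden index
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC thresholds;
#' ties are broken toward the lowest threshold (highest sensitivity).
#'
#' @param roc An `icas_roc` from [roc_curve()].
#' @return A list: `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_optimal <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  i <- which(j == max(j))[1L]  # thresholds ascend, so first max = lowest
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], youden = j[i])
}

#' Cross-validated forest evaluation
#'
#' Fits one forest per fold on the training folds only and scores the
#' held-out subjects by their patient vote fraction; pooled out-of-fold
#' scores give accuracy, the ROC curve/AUC and the Youden operating point.
#'
#' @param x Feature matrix or `icas_features` table.
#' @param y Class labels.
#' @param folds Integer fold ids (see [make_folds()]); generated at `k = 10`
#'   when absent.
#' @param n_trees,mtry Forest parameters.
#' @param seed Optional integer seed (used for fold generation when `folds`
#'   is missing, and for tree growing).
#' @return A list of class `icas_cv`: `scores` (out-of-fold vote fractions),
#'   `label`, `folds`, `accuracy`, `roc`, `auc`, `youden`.
#' @export
cross_validate <- function(x, y = NULL, folds = NULL, n_trees = 300L,
                           mtry = NULL, seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  y01 <- .as_class01(y)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- make_folds(y01, k = min(10L, nrow(x)))
  scores <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2)
      stop("training split of fold ", f, " contains a single class")
    forest <- fit_forest(x[tr, , drop = FALSE], y01[tr], n_trees = n_trees,
                         mtry = mtry)
    scores[!tr] <- predict(forest, x[!tr, , drop = FALSE])$vote_icas
  }
  label <- ifelse(scores > 0.5, 1L, 0L)
  roc <- roc_curve(scores, y01)
  structure(list(scores = scores, label = label, folds = folds,
                 accuracy = mean(label == y01), roc = roc, auc = roc$auc,
                 youden = youden_optimal(roc)),
            class = "icas_cv")
}

# DeLong's test ---------------------------------------------------------------

.midrank <- function(v) rank(v, ties.method = "average")

# Fast DeLong structural components for one score vector (midrank based).
.delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  tz <- .midrank(c(xs, ys))
  tx <- .midrank(xs); ty <- .midrank(ys)
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v01 <- (tz[seq_len(m)] - tx) / n            # per-positive components
  v10 <- 1 - (tz[m + seq_len(n)] - ty) / m    # per-negative components
  list(auc = auc, v01 = v01, v10 = v10, m = m, n = n)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same subjects via
#' the fast midrank formulation of DeLong's covariance estimate. Identical
#' scores (zero variance of the difference with equal AUCs) give `z = 0`,
#' `p = 1`.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Class labels shared by both.
#' @return A list of class `delong_result`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- .as_class01(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; y <- y[keep]
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be present")
  a <- .delong_components(scores_a, y)
  b <- .delong_components(scores_b, y)
  s01 <- cov(cbind(a$v01, b$v01))
  s10 <- cov(cbind(a$v10, b$v10))
  S <- s01 / a$m + s10 / a$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < .Machine$double.eps) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- 2 * pnorm(-abs(z))
  structure(list(auc_a = a$auc, auc_b = b$auc, var_diff = var_diff,
                 z = z, p = p),
            class = "delong_result")
}

# Higher-level comparisons ----------------------------------------------------

#' Repeat an evaluation closure over derived seeds
#'
#' Reruns `fn(seed)` with `n_repetitions` independently derived seeds and
#' summarizes every numeric metric it returns by mean and SD. Accuracies are
#' reported without significance testing across repetitions (cross-validation
#' training sets overlap, so no unbiased variance estimator exists).
#'
#' @param fn Function of one argument (a seed) returning a named numeric
#'   vector or list of metrics.
#' @param n_repetitions Number of reruns.
#' @param seed Master seed.
#' @return A list: `mean`, `sd` (named vectors), `runs` (matrix of per-run
#'   metrics).
#' @export
repeat_evaluation <- function(fn, n_repetitions = 100L, seed = NULL) {
  seeds <- .derive_seeds(n_repetitions, seed)
  runs <- NULL
  for (r in seq_len(n_repetitions)) {
    res <- unlist(fn(seeds[r]))
    if (is.null(runs)) runs <- matrix(NA_real_, n_repetitions, length(res),
                                      dimnames = list(NULL, names(res)))
    runs[r, ] <- res
  }
  list(mean = colMeans(runs),
       sd = if (n_repetitions > 1) apply(runs, 2L, sd)
            else setNames(rep(0, ncol(runs)), colnames(runs)),
       runs = runs)
}

#' Compare VOI definitions (whole GM/WM vs iWSA-resolved vs inside-only)
#'
#' Cross-validates forests on the three feature-table modes of the same
#' cohort over repeated fold assignments, reporting mean and SD of accuracy
#' and AUC per mode, plus pairwise DeLong tests on the per-subject
#' out-of-fold scores averaged across repetitions.
#'
#' @param cohort An `icas_cohort`.
#' @param n_repetitions Fold-assignment repetitions.
#' @param k Folds.
#' @param n_trees Trees per forest.
#' @param seed Master seed.
#' @return A list: `summary` (data frame mode/accuracy/auc with SDs),
#'   `delong` (data frame of pairwise tests), `mean_scores` (matrix).
#' @export
compare_voi_definitions <- function(cohort, n_repetitions = 10L, k = 10L,
                                    n_trees = 300L, seed = NULL) {
  stopifnot(inherits(cohort, "icas_cohort"))
  modes <- c("whole", "iwsa", "inside_only")
  tables <- lapply(modes, function(m) assemble_features(cohort, m))
  names(tables) <- modes
  seeds <- .derive_seeds(n_repetitions, seed)
  n <- length(cohort$group)
  acc <- auc <- matrix(NA_real_, n_repetitions, length(modes),
                       dimnames = list(NULL, modes))
  score_sum <- matrix(0, n, length(modes), dimnames = list(NULL, modes))
  for (r in seq_len(n_repetitions)) {
    set.seed(seeds[r])
    folds <- make_folds(cohort$group, k = k)
    for (m in modes) {
      cv <- cross_validate(tables[[m]], folds = folds, n_trees = n_trees)
      acc[r, m] <- cv$accuracy; auc[r, m] <- cv$auc
      score_sum[, m] <- score_sum[, m] + cv$scores
    }
  }
  mean_scores <- score_sum / n_repetitions
  pairs <- utils::combn(modes, 2L)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    d <- delong_test(mean_scores[, pairs[1, i]], mean_scores[, pairs[2, i]],
                     cohort$group)
    data.frame(mode_a = pairs[1, i], mode_b = pairs[2, i],
               auc_a = d$auc_a, auc_b = d$auc_b, z = d$z, p = d$p,
               stringsAsFactors = FALSE)
  }))
  summary <- data.frame(
    mode = modes,
    n_features = vapply(tables, function(t) ncol(t$x), integer(1)),
    accuracy_mean = colMeans(acc), accuracy_sd = apply(acc, 2L, sd),
    auc_mean = colMeans(auc), auc_sd = apply(auc, 2L, sd),
    stringsAsFactors = FALSE, row.names = NULL)
  list(summary = summary, delong = delong, mean_scores = mean_scores)
}

#' Nested cross-validated feature selection
#'
#' Within each outer fold, using the training rows only: computes
#' repetition-averaged OOB permutation importances on the full feature set,
#' keeps the best VOI and best VOI-difference per parameter
#' ([per_parameter_dedup()]), sorts by descending score and truncates to
#' `max_size` candidates; then trains one forest per nested size
#' `s = 1..max_size` on the top-`s` features and scores the held-out fold.
#' Pooling across folds yields one out-of-fold score vector, accuracy and
#' AUC per size. The selection function receives only the training
#' partition, so the held-out rows cannot influence which features are
#' chosen.
#'
#' @inheritParams cross_validate
#' @param max_size Largest nested model size.
#' @param inner_repetitions Importance repetitions inside each outer fold.
#' @return A list of class `icas_nested_cv`: `per_size` (data frame
#'   `size`, `accuracy`, `auc`), `best_size` (argmax AUC), `scores` (matrix
#'   subjects x sizes), `selected` (list of per-fold candidate rankings),
#'   `best` (the `icas_cv`-like summary of the best size).
#' @export
nested_feature_selection_cv <- function(x, y = NULL, folds = NULL,
                                        max_size = 12L,
                                        inner_repetitions = 100L,
                                        n_trees = 300L, seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  y01 <- .as_class01(y)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- make_folds(y01, k = min(10L, nrow(x)))
  sizes <- seq_len(max_size)
  scores <- matrix(NA_real_, nrow(x), max_size)
  selected <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2)
      stop("training split of fold ", f, " contains a single class")
    ranking <- .select_features(x[tr, , drop = FALSE], y01[tr],
                                inner_repetitions, n_trees, max_size)
    selected[[as.character(f)]] <- ranking
    for (s in sizes) {
      feats <- ranking$feature[seq_len(min(s, nrow(ranking)))]
      forest <- fit_forest(x[tr, feats, drop = FALSE], y01[tr],
                           n_trees = n_trees)
      scores[!tr, s] <- predict(forest,
                                x[!tr, feats, drop = FALSE])$vote_icas
    }
  }
  per_size <- data.frame(
    size = sizes,
    accuracy = vapply(sizes, function(s)
      mean((scores[, s] > 0.5) == (y01 == 1L)), numeric(1)),
    auc = vapply(sizes, function(s) roc_curve(scores[, s], y01)$auc,
                 numeric(1)))
  best_size <- per_size$size[which.max(per_size$auc)]
  roc <- roc_curve(scores[, best_size], y01)
  structure(list(per_size = per_size, best_size = best_size, scores = scores,
                 selected = selected,
                 best = list(accuracy = per_size$accuracy[best_size],
                             auc = per_size$auc[best_size], roc = roc,
                             youden = youden_optimal(roc))),
            class = "icas_nested_cv")
}

# Inner-loop candidate ranking: importance on the training partition only,
# deduplicated per parameter, truncated to max_size.
.select_features <- function(x_train, y_train, inner_repetitions, n_trees,
                             max_size) {
  imp <- repeated_importance(x_train, y_train,
                             n_repetitions = inner_repetitions,
                             n_trees = n_trees)
  dd <- per_parameter_dedup(imp)
  dd[seq_len(min(max_size, nrow(dd))), , drop = FALSE]
}
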