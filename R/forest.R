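# R interface to the bagged classification-tree ensemble.

.as_feature_matrix <- function(x) {
  if (inherits(x, "icas_features")) x <- x$x
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

.as_class01 <- function(y, levels = c("HC", "ICAS")) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% levels)) stop("unknown class labels: ",
                                  paste(setdiff(y, levels), collapse = ", "))
    return(as.integer(y == levels[2L]))
  }
  as.integer(y != 0)
}

#' Fit a bagged classification-tree ensemble
#'
#' Grows `n_trees` CART-style classification trees, each on a bootstrap
#' sample of the subjects (drawn with replacement, in-bag/out-of-bag
#' membership recorded). At every node a random subset of `mtry` features is
#' drawn and the Gini-optimal threshold among rows with the candidate
#' observed is chosen; up to `max_surrogates` surrogate splits ranked by
#' agreement with the primary split route rows with missing values, with the
#' majority child as last resort. Trees are grown to purity. Prediction is
#' the majority vote over trees; vote ties go to the control class.
#'
#' @param x Feature matrix (subjects x features; `NA` = missing) or an
#'   `icas_features` table.
#' @param y Class labels (factor/character with levels `HC`, `ICAS`, or
#'   0/1 with 1 the patient class). Taken from `x` when it is an
#'   `icas_features` table.
#' @param n_trees Number of bootstrapped trees.
#' @param mtry Features drawn per node; default `floor(sqrt(p))`.
#' @param max_surrogates Surrogate splits retained per node.
#' @param seed Optional integer seed.
#' @return A list of class `icas_forest`.
#' @export
fit_forest <- function(x, y = NULL, n_trees = 300L, mtry = NULL,
                       max_surrogates = 5L, seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  x <- .as_feature_matrix(x)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (all(is.na(x))) stop("feature matrix is entirely missing")
  y01 <- .as_class01(y)
  if (length(y01) != nrow(x)) stop("length(y) must match nrow(x)")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  mtry <- min(as.integer(mtry), ncol(x))
  if (!is.null(seed)) set.seed(seed)
  trees <- .rf_fit_cpp(x, y01, as.integer(n_trees), mtry,
                       as.integer(max_surrogates))
  structure(list(trees = trees, x = x, y = y01,
                 features = colnames(x), n_trees = as.integer(n_trees),
                 mtry = mtry, max_surrogates = as.integer(max_surrogates),
                 levels = c("HC", "ICAS"), seed = seed),
            class = "icas_forest")
}

#' @export
print.icas_forest <- function(x, ...) {
  cat("Bagged classification-tree ensemble:", x$n_trees, "trees,",
      length(x$features), "features (mtry =", x$mtry, ")\n")
  oob <- oob_predict(x)
  cat("OOB error:", sprintf("%.3f\n", oob$error))
  invisible(x)
}

#' Predict classes and vote fractions
#'
#' @param object An `icas_forest`.
#' @param newdata Feature matrix with the training feature universe
#'   (columns matched by name); defaults to the training data.
#' @param ... Unused.
#' @return A list: `label` (factor), `vote_icas` (fraction of trees voting
#'   for the patient class).
#' @export
predict.icas_forest <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else .as_feature_matrix(newdata)
  if (!is.null(newdata)) {
    missing_cols <- setdiff(object$features, colnames(x))
    extra <- setdiff(colnames(x), object$features)
    if (length(missing_cols) > 0 || length(extra) > 0)
      stop("feature columns do not match the training universe",
           if (length(extra) > 0)
             paste0(" (unknown: ", paste(extra, collapse = ", "), ")"))
    x <- x[, object$features, drop = FALSE]
  }
  votes <- .rf_predict_cpp(object$trees, x)
  frac <- votes[, 2L] / rowSums(votes)
  label <- factor(ifelse(frac > 0.5, "ICAS", "HC"), levels = object$levels)
  list(label = label, vote_icas = frac)
}

#' Out-of-bag predictions
#'
#' Aggregates, per subject, the votes of only those trees whose bootstrap
#' sample did not contain the subject. Subjects that are in-bag everywhere
#' get `NA` (counted in `n_unscored`).
#'
#' @param forest An `icas_forest`.
#' @return A list: `vote_icas`, `label`, `n_oob_trees`, `error` (OOB
#'   misclassification rate over scored subjects), `n_unscored`.
#' @export
oob_predict <- function(forest) {
  stopifnot(inherits(forest, "icas_forest"))
  votes <- .rf_oob_votes_cpp(forest$trees, forest$x)
  n_oob <- rowSums(votes)
  frac <- ifelse(n_oob > 0, votes[, 2L] / n_oob, NA_real_)
  label <- factor(ifelse(frac > 0.5, "ICAS", "HC"), levels = forest$levels)
  label[is.na(frac)] <- NA
  scored <- !is.na(frac)
  err <- mean((frac[scored] > 0.5) != (forest$y[scored] == 1L))
  list(vote_icas = frac, label = label, n_oob_trees = n_oob,
       error = err, n_unscored = sum(!scored))
}

#' Out-of-bag permutation feature importance
#'
#' For each tree, the OOB error is recomputed after permuting one feature's
#' values across that tree's OOB subjects (a fresh permutation per tree).
#' The per-feature score is the mean error increase over trees divided by
#' its standard deviation across trees (0 when the SD is 0, e.g. for
#' features no tree uses).
#'
#' @param forest An `icas_forest`.
#' @param seed Optional integer seed for the permutations.
#' @return Named numeric vector of importance scores.
#' @export
permutation_importance <- function(forest, seed = NULL) {
  stopifnot(inherits(forest, "icas_forest"))
  if (!is.null(seed)) set.seed(seed)
  setNames(.rf_importance_cpp(forest$trees, forest$x, forest$y),
           forest$features)
}

# JSON serialization ----------------------------------------------------------

#' Serialize a forest to JSON
#'
#' Writes the complete ensemble — per-tree node tables (split feature,
#' threshold, children, class counts, fallback direction), surrogate tables,
#' and in-bag counts — plus the feature universe and seed, to a documented
#' JSON structure that [read_forest_json()] restores to a predicting forest.
#'
#' @param forest An `icas_forest`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_forest_json <- function(forest, path) {
  stopifnot(inherits(forest, "icas_forest"))
  trees <- lapply(forest$trees, function(tr) {
    list(nodes = as.data.frame(tr$nodes),
         surrogates = as.data.frame(tr$surrogates),
         inbag = tr$inbag)
  })
  jsonlite::write_json(
    list(format = "carotidrf-forest-1",
         levels = forest$levels, features = forest$features,
         n_trees = forest$n_trees, mtry = forest$mtry,
         max_surrogates = forest$max_surrogates,
         seed = forest$seed, trees = trees),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_forest_json
#' @param x Training feature matrix to reattach (needed for OOB operations;
#'   optional for prediction).
#' @param y Training labels to reattach.
#' @export
read_forest_json <- function(path, x = NULL, y = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "carotidrf-forest-1"))
    stop("not a serialized carotidrf forest")
  fix <- function(df, cols) {
    m <- as.matrix(df)
    if (length(m) == 0) m <- matrix(numeric(0), 0, length(cols))
    colnames(m) <- cols
    m
  }
  trees <- lapply(seq_len(obj$n_trees), function(i) {
    tr <- if (is.data.frame(obj$trees)) obj$trees[i, ] else obj$trees[[i]]
    list(nodes = fix(if (is.data.frame(tr)) tr$nodes[[1]] else tr$nodes,
                     c("feature", "threshold", "left", "right", "n0", "n1",
                       "fallback")),
         surrogates = fix(if (is.data.frame(tr)) tr$surrogates[[1]] else tr$surrogates,
                          c("node", "feature", "threshold", "dir", "agreement")),
         inbag = as.integer(if (is.data.frame(tr)) tr$inbag[[1]] else tr$inbag))
  })
  out <- list(trees = trees, x = x, y = if (is.null(y)) NULL else .as_class01(y),
              features = obj$features, n_trees = obj$n_trees,
              mtry = obj$mtry, max_surrogates = obj$max_surrogates,
              levels = obj$levels, seed = obj$seed)
  class(out) <- "icas_forest"
  out
}
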