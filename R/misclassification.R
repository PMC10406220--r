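# Per-subject misclassification probabilities and the cognition subanalysis.

#' Per-subject misclassification probability
#'
#' Fits `n_repetitions` independently seeded forests on the full cohort and,
#' per repetition, compares each subject's out-of-bag prediction with the
#' true class. The misclassification probability is the number of incorrect
#' predictions divided by the number of repetitions in which the subject was
#' out of bag at least once (repetitions without an OOB prediction for a
#' subject are excluded from that subject's denominator).
#'
#' @param x Feature matrix or `icas_features` table (the full feature set).
#' @param y Class labels.
#' @param n_repetitions Number of repeated forests.
#' @param n_trees Trees per forest.
#' @param seed Master seed.
#' @return A data frame of class `icas_misclass`: `id`, `group`,
#'   `n_scored`, `n_incorrect`, `probability`; attribute
#'   `prediction_source = "oob"`.
#' @export
misclassification_probability <- function(x, y = NULL, n_repetitions = 1000L,
                                          n_trees = 300L, seed = NULL) {
  if (inherits(x, "icas_features") && is.null(y)) y <- x$y
  ids <- if (inherits(x, "icas_features")) x$id else rownames(.as_feature_matrix(x))
  xm <- .as_feature_matrix(x)
  y01 <- .as_class01(y)
  seeds <- .derive_seeds(n_repetitions, seed)
  n <- nrow(xm)
  n_scored <- n_incorrect <- integer(n)
  for (r in seq_len(n_repetitions)) {
    set.seed(seeds[r])
    forest <- fit_forest(xm, y01, n_trees = n_trees)
    oob <- oob_predict(forest)
    scored <- !is.na(oob$vote_icas)
    wrong <- scored & ((oob$vote_icas > 0.5) != (y01 == 1L))
    n_scored <- n_scored + scored
    n_incorrect <- n_incorrect + wrong
  }
  out <- data.frame(
    id = if (is.null(ids)) sprintf("S%03d", seq_len(n)) else ids,
    group = factor(ifelse(y01 == 1L, "ICAS", "HC"), levels = c("HC", "ICAS")),
    n_scored = n_scored, n_incorrect = n_incorrect,
    probability = ifelse(n_scored > 0, n_incorrect / n_scored, NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "prediction_source") <- "oob"
  attr(out, "n_repetitions") <- n_repetitions
  class(out) <- c("icas_misclass", "data.frame")
  out
}

#' Threshold misclassification probabilities into patient subgroups
#'
#' Patients with misclassification probability strictly above `threshold`
#' form the frequently-misclassified subgroup; the rest (including exactly
#' `threshold`) the correctly-classified subgroup. Controls are excluded.
#'
#' @param profile An `icas_misclass` data frame.
#' @param threshold Probability cutoff.
#' @return A list: `correct` and `misclassified` (character vectors of
#'   patient ids), `threshold`.
#' @export
split_subgroups <- function(profile, threshold = 0.50) {
  stopifnot(inherits(profile, "icas_misclass"))
  pat <- profile[profile$group == "ICAS" & !is.na(profile$probability), ]
  list(correct = pat$id[pat$probability <= threshold],
       misclassified = pat$id[pat$probability > threshold],
       threshold = threshold)
}

#' Compare clinical and cognitive measures between patient subgroups
#'
#' For each measure, compares the correctly-classified and misclassified
#' patient subgroups: continuous measures use a two-tailed t-test when both
#' subgroups pass a Shapiro-Wilk normality screen (and have non-zero
#' variance), otherwise the Mann-Whitney U test (exact when feasible, normal
#' approximation with tie correction otherwise); both test results are
#' reported side by side. Patients with a missing value of a measure are
#' excluded from that measure's comparison.
#'
#' @param cohort The `icas_cohort`.
#' @param subgroups A list from [split_subgroups()].
#' @param measures Clinical columns to compare.
#' @param alpha Significance threshold for the decision flag.
#' @param normality_alpha Shapiro-Wilk screening level.
#' @return A data frame: per measure, subgroup means and SDs and sizes, the
#'   chosen test, its statistic and two-sided p, the Mann-Whitney p, and the
#'   `significant` flag at `alpha`.
#' @export
compare_subgroups <- function(cohort, subgroups,
                              measures = c("tmt_a", "tmt_b", "mmse", "bdi",
                                           "stai", "age", "nascet"),
                              alpha = 0.05, normality_alpha = 0.05) {
  stopifnot(inherits(cohort, "icas_cohort"))
  if (length(subgroups$correct) == 0 || length(subgroups$misclassified) == 0) {
    warning("a subgroup is empty; comparison skipped")
    return(NULL)
  }
  cl <- cohort$clinical
  rows <- lapply(measures, function(m) {
    a <- cl[[m]][match(subgroups$correct, cohort$id)]
    b <- cl[[m]][match(subgroups$misclassified, cohort$id)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(measure = m, n_correct = length(a),
                        n_misclassified = length(b),
                        correct_mean = mean(a), correct_sd = sd(a),
                        misclassified_mean = mean(b), misclassified_sd = sd(b),
                        test = NA_character_, statistic = NA_real_,
                        p = NA_real_, p_mannwhitney = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    normal <- sd(a) > 0 && sd(b) > 0 &&
      shapiro.test(a)$p.value > normality_alpha &&
      shapiro.test(b)$p.value > normality_alpha
    mw <- suppressWarnings(wilcox.test(a, b, exact = !any(duplicated(c(a, b))),
                                       correct = TRUE))
    if (normal) {
      tt <- t.test(a, b)
      test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      test <- "mannwhitney"; statistic <- unname(mw$statistic); p <- mw$p.value
    }
    data.frame(measure = m, n_correct = length(a),
               n_misclassified = length(b),
               correct_mean = mean(a), correct_sd = sd(a),
               misclassified_mean = mean(b), misclassified_sd = sd(b),
               test = test, statistic = statistic, p = p,
               p_mannwhitney = mw$p.value, significant = p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
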