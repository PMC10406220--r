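#!/usr/bin/env Rscript
# Rank the 96 iWSA-resolved features by repetition-averaged out-of-bag
# permutation importance, then reduce them by recursive elimination and
# per-parameter deduplication, and validate the ranking on random
# 12-feature subsets. Repetition counts are scaled down from the
# 1,000-repetition reference procedure for a desk-scale run.

suppressPackageStartupMessages(library(carotidrf))
dir.create("results", showWarnings = FALSE)

cohort_tab <- read_feature_csv("results/cohort.csv")
x <- cohort_tab$x[, feature_names("iwsa")]
y <- cohort_tab$y

imp <- repeated_importance(x, y, n_repetitions = 50, n_trees = 100, seed = 3)
write.csv(imp, "results/importance.csv", row.names = FALSE)
cat("Top 7 features by mean importance score (50-repetition average):\n")
print(head(imp[, c("feature", "mean", "sd", "rank")], 7), row.names = FALSE)

rfe <- recursive_feature_elimination(x, y, n_repetitions = 10, n_trees = 100,
                                     seed = 4)
cat("\nRecursive elimination:", attr(rfe, "n_iterations"), "iterations,",
    nrow(rfe), "survivors with score > 0.1\n")

final <- per_parameter_dedup(rfe)
write.csv(final, "results/final_features.csv", row.names = FALSE)
cat("\nFinal model features after per-parameter deduplication:\n")
print(final[, c("feature", "mean", "rank")], row.names = FALSE)

# Bar figure: 12 VOIs per parameter in canonical order
pdf("results/importance_scores.pdf", width = 11, height = 5)
ord <- match(feature_names("iwsa"), imp$feature)
cols <- rep(rep(c("#c23b22", "#e6b422", "#3a7d44", "#2b6cb0"), 3), 8)
par(mar = c(9, 4, 2, 1))
bp <- barplot(imp$mean[ord], col = cols, border = NA,
              ylab = "mean importance score", las = 2,
              names.arg = rep("", 96))
text(bp[seq(6, 96, by = 12)], par("usr")[3] - 0.02 * diff(par("usr")[3:4]),
     labels = mri_parameters(), xpd = NA, srt = 0)
legend("topright", bty = "n", fill = c("#c23b22", "#e6b422", "#3a7d44",
                                       "#2b6cb0"),
       legend = c("GM inside", "GM outside", "WM inside", "WM outside"))
invisible(dev.off())
cat("\nfigure written to results/importance_scores.pdf\n")

rsv <- random_subset_validation(x, y, subset_size = 12, n_subsets = 60,
                                n_trees = 100, full_ranking = imp, seed = 5)
cat(sprintf("\nRandom 12-feature subset validation: Spearman rho = %.2f %s\n",
            rsv$spearman,
            "between subset-based and full-set rankings"))
top_stable <- rsv$per_feature[order(rsv$per_feature$mean_norm_rank), ][1:5, ]
cat("Most stable top features across subsets:\n")
print(top_stable, row.names = FALSE)
write.csv(rsv$per_feature, "results/subset_validation.csv", row.names = FALSE)
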