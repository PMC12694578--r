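#!/usr/bin/env Rscript
# Group-level statistics: misclassification exclusion, inter-fold agreement,
# pairwise Kendall correlation, node scores, functional-network contrast,
# and saliency-clinical-metric associations over the PD cohort.

suppressPackageStartupMessages(library(voxsal))
sim <- readRDS("scratch/sim/sim.rds")
cv <- readRDS("scratch/models/cv.rds")
maps <- readRDS("scratch/sal/maps.rds")
atlas <- sim$atlas
mat <- regional_matrix(maps$normalized, atlas)     # profiles / correlation
mat_raw <- regional_matrix(maps$raw, atlas)        # clinical association
subjects <- cv$subjects

ex <- exclude_misclassified(subjects)
cat(sprintf("excluded %d/%d PD and %d/%d CT misclassified subjects\n",
            ex$report[["PD"]], sum(subjects$true_class == "PD"),
            ex$report[["CT"]], sum(subjects$true_class == "CT")))

fm <- fold_mean_matrix(mat, subjects)
reg <- interfold_regression(fm)
write.csv(reg, "results/interfold_regression.csv", row.names = FALSE)
cat(sprintf("inter-fold regression slopes: %s\n",
            paste(sprintf("%.2f", reg$b1), collapse = ", ")))

pd_keep <- ex$keep & subjects$true_class == "PD"
ct <- pairwise_kendall(mat[pd_keep, , drop = FALSE])
write.csv(ct$tau, "results/kendall_tau.csv")
write.csv(ct$pvals, "results/kendall_pvals.csv")

ns <- node_scores(ct)
write.csv(data.frame(area = names(ns), node_score = ns),
          "results/node_scores.csv", row.names = FALSE)
cat("highest node-score areas:\n")
print(head(sort(ns, decreasing = TRUE), 5))

con <- network_contrast(ct, atlas$labels$networks)
write.csv(con, "results/network_contrast.csv", row.names = FALSE)
planted <- atlas$labels$networks[sim$cohort$effect_areas[1]]
crow <- con[con$network == planted, ]
cat(sprintf("planted network %s: intra tau %.3f vs all-areas %.3f\n",
            planted, crow$intra_mean, crow$all_mean))

# statistic volume for visualization parity
RNifti::writeNifti(stat_volume(ns, atlas), "scratch/node_scores.nii.gz")

assoc_all <- list()
for (metric in c("updrs_p3", "moca", "ledd", "years_onset")) {
  a <- tryCatch(metric_association(mat_raw, subjects, metric),
                error = function(e) NULL)
  if (is.null(a)) {
    cat(sprintf("%s: skipped (insufficient subjects)\n", metric))
    next
  }
  assoc_all[[metric]] <- a
  cat(sprintf("%s: %d/%d areas significant (n = %d)\n", metric,
              sum(a$pearson_significant), nrow(a), a$n[1]))
}
write.csv(do.call(rbind, assoc_all), "results/metric_associations.csv",
          row.names = FALSE)
mp <- metric_pairwise(subjects)
write.csv(mp, "results/metric_pairwise.csv", row.names = FALSE)
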