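#!/usr/bin/env Rscript
# Convert voxelwise saliency into per-area regional scores through the
# probabilistic atlas, then aggregate to class profiles and lobe profiles
# (correctly classified subjects only).

suppressPackageStartupMessages(library(voxsal))
sim <- readRDS("scratch/sim/sim.rds")
cv <- readRDS("scratch/models/cv.rds")
maps <- readRDS("scratch/sal/maps.rds")

mat <- regional_matrix(maps$normalized, sim$atlas)
write.csv(data.frame(id = rownames(mat), mat, check.names = FALSE),
          "results/regional_saliency.csv", row.names = FALSE)
mat_raw <- regional_matrix(maps$raw, sim$atlas)
write.csv(data.frame(id = rownames(mat_raw), mat_raw, check.names = FALSE),
          "results/regional_saliency_raw.csv", row.names = FALSE)

prof <- class_profiles(mat, cv$subjects)
write.csv(prof, "results/class_profiles.csv", row.names = FALSE)
lobes <- lobe_aggregate(mat, sim$atlas, cv$subjects)
write.csv(lobes, "results/lobe_profiles.csv", row.names = FALSE)

pd <- prof[prof$class == "PD", ]
top <- head(order(pd$mean, decreasing = TRUE), 8)
eff <- sim$cohort$effect_areas
cat("top PD-class areas by mean regional saliency:\n")
print(pd[top, c("area", "mean", "half_width")], row.names = FALSE)
cat(sprintf("planted areas among the top 20%%: %d of %d\n",
            sum(eff %in% top), length(eff)))
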