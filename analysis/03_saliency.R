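#!/usr/bin/env Rscript
# Compute one GradCAM saliency volume per subject from the fold where the
# subject was held out, on the predicted-class channel, normalized to unit
# mean; write them as NIfTI under scratch/sal/.

suppressPackageStartupMessages(library(voxsal))
sim <- readRDS("scratch/sim/sim.rds")
cv <- readRDS("scratch/models/cv.rds")

# raw maps keep per-subject evidence magnitude; the normalized copies put
# subjects on a common mean-1 scale for group profiles
raw_maps <- holdout_maps(cv$models, cv$subjects, sim$cohort$volumes,
                         normalize = FALSE)
maps <- lapply(raw_maps, normalize_map)
dir.create("scratch/sal", showWarnings = FALSE, recursive = TRUE)
for (m in maps)
  RNifti::writeNifti(m$values,
                     sprintf("scratch/sal/%s_%d_%s.nii.gz",
                             m$subject_id, m$fold, m$class_channel))
saveRDS(list(raw = raw_maps, normalized = maps), "scratch/sal/maps.rds")

zeros <- sum(vapply(maps, `[[`, logical(1), "all_zero"))
cat(sprintf("wrote %d hold-out saliency maps (%d degenerate all-zero)\n",
            length(maps), zeros))
cat(sprintf("class channels: %s\n",
            paste(names(table(vapply(maps, `[[`, character(1),
                                     "class_channel"))),
                  table(vapply(maps, `[[`, character(1), "class_channel")),
                  sep = "=", collapse = ", ")))
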