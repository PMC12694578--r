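#!/usr/bin/env Rscript
# Train the reduced-width 3D residual classifier with stratified 4-fold
# cross-validation at the fixed hyperparameters (ADAM, batch 10, 20 epochs,
# lr 3e-4, L2 5e-4, fc learning-rate scalar 5, harmonization augmentation
# each epoch), predict every held-out subject, and summarize performance.

suppressPackageStartupMessages(library(voxsal))
cfg <- yaml::read_yaml(file.path("analysis", "cohort.yaml"))
sim <- readRDS("scratch/sim/sim.rds")

cv <- run_cv(sim$cohort$volumes, sim$cohort$subjects,
             k = cfg$training$k, spec = recovery_architecture(),
             config = train_config(seed = cfg$seed), seed = cfg$seed)

dir.create("scratch/models", showWarnings = FALSE, recursive = TRUE)
for (f in seq_along(cv$models))
  save_model(cv$models[[f]], sprintf("scratch/models/fold%d", f))
saveRDS(cv, "scratch/models/cv.rds")

pred <- cv$subjects[, c("id", "fold", "true_class", "predicted_class",
                        "score_CT", "score_PD")]
write.csv(pred, "results/predictions.csv", row.names = FALSE)
ev <- evaluate_cv(cv$subjects)
write.csv(ev$per_fold, "results/eval_per_fold.csv", row.names = FALSE)
write.csv(ev$pooled, "results/eval_pooled.csv", row.names = FALSE)

cat("per-fold held-out performance:\n")
print(ev$per_fold, row.names = FALSE)
acc <- ev$pooled[ev$pooled$metric == "accuracy", ]
cat(sprintf("pooled accuracy: %.3f +/- %.3f (95%% half-width across folds)\n",
            acc$mean, acc$half_width))
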