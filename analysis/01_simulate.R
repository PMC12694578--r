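#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: a probabilistic blob atlas and
# per-subject volumes with a planted network-structured intensity reduction
# in the first functional network, plus severity-coupled clinical scores.
# Writes volumes/atlas (NIfTI) under scratch/sim/ and the subject table under
# results/.

suppressPackageStartupMessages(library(voxsal))
cfg <- yaml::read_yaml(file.path("analysis", "cohort.yaml"))

atlas <- make_atlas(cfg$atlas$n_areas, unlist(cfg$cohort$grid_shape),
                    n_networks = cfg$atlas$n_networks, seed = cfg$seed,
                    n_lobes = cfg$atlas$n_lobes,
                    sigma_range = unlist(cfg$atlas$sigma_range),
                    min_separation = cfg$atlas$min_separation)
validate_atlas(atlas)
spec <- cohort_spec(n_per_class = cfg$cohort$n_per_class,
                    grid_shape = unlist(cfg$cohort$grid_shape),
                    effect_size = cfg$cohort$effect_size,
                    seed = cfg$seed)
cohort <- make_cohort(spec, atlas)

dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
write_atlas(atlas, "scratch/sim/atlas")
write_cohort(cohort, "scratch/sim/cohort")
saveRDS(list(atlas = atlas, cohort = cohort, spec = spec),
        "scratch/sim/sim.rds")
write.csv(cohort$subjects, "results/subjects.csv", row.names = FALSE)

eff <- cohort$effect_areas
cat(sprintf("cohort: %d subjects (%d per class) on a %s grid\n",
            nrow(cohort$subjects), spec$n_per_class,
            paste(spec$grid_shape, collapse = "x")))
cat(sprintf("planted effect: %d areas of network %s (%s), delta = %g\n",
            length(eff), atlas$labels$networks[eff[1]],
            paste(atlas$labels$name[eff], collapse = ", "),
            spec$effect_size))
pd <- cohort$subjects$true_class == "PD"
cat(sprintf("PD severity: median %.2f, UPDRS-analogue mean %.1f, MoCA-analogue mean %.1f\n",
            median(cohort$subjects$latent_severity[pd]),
            mean(cohort$subjects$updrs_p3[pd], na.rm = TRUE),
            mean(cohort$subjects$moca[pd], na.rm = TRUE)))
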