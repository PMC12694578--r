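#' Reduced-width architecture for desk-scale recovery runs
#'
#' Same family as the full classifier (wide-kernel stride-2 stem, basic
#' residual blocks, batch norm everywhere, spatial-dropout head) but narrow
#' (6/12 channels) and without the stem max pool, so the designated GradCAM
#' layer keeps an 8^3 feature grid on 32^3 inputs — enough spatial resolution
#' to localize planted regional effects. The spatial-dropout probability is
#' 0.2 rather than the full model's 0.4: channel dropout scales badly to very
#' narrow heads (at 12 channels, p = 0.4 silences five expected feature maps
#' per sample, which stalls optimization at this width).
#' @export
recovery_architecture <- function() {
  architecture_spec(stem_channels = 6L, stem_pool = FALSE,
                    stages = list(c(1L, 6L), c(1L, 12L)),
                    dropout = 0.2)
}

#' Default desk-scale recovery settings
#'
#' A 60-subject cohort (30 per class) on a 32^3 grid with a 40-area,
#' 8-network atlas; the planted effect covers every area of the first
#' network. Atlas areas are spaced at least 6 voxels apart so regional
#' saliency can separate them at the reduced feature resolution.
#' @param seed integer seed controlling atlas, cohort and training.
#' @return list of settings consumed by [run_recovery()].
#' @export
recovery_settings <- function(seed = 1L) {
  list(seed = as.integer(seed),
       n_areas = 40L, n_networks = 8L,
       grid_shape = c(32L, 32L, 32L),
       n_per_class = 30L,
       k = 4L,
       min_separation = 6,
       sigma_range = c(1.8, 2.6),
       arch = recovery_architecture())
}

#' End-to-end planted-effect recovery run
#'
#' Generates a synthetic cohort with a planted network-structured regional
#' effect, trains the reduced-width classifier with 4-fold cross-validation
#' at the standard hyperparameters, computes hold-out GradCAM maps, regional
#' scores, and the association statistics, and summarizes whether the
#' pipeline recovered the planted structure.
#'
#' @param seed integer seed.
#' @param settings list from [recovery_settings()].
#' @return list with the fitted objects plus a `criteria` list: held-out
#'   `accuracy`, `effect_in_top20` (every planted area in the top 20 percent
#'   of the PD-class mean regional saliency profile),
#'   `assoc_positive_significant` (the pooled raw saliency over planted
#'   areas is positively and significantly associated with the UPDRS
#'   analogue), and `network_contrast_ok` (intra-network mean tau above the
#'   all-areas mean for the planted network).
#' @export
run_recovery <- function(seed = 1L, settings = recovery_settings(seed)) {
  atlas <- make_atlas(settings$n_areas, settings$grid_shape,
                      n_networks = settings$n_networks, seed = settings$seed,
                      min_separation = settings$min_separation,
                      sigma_range = settings$sigma_range)
  cspec <- cohort_spec(n_per_class = settings$n_per_class,
                       grid_shape = settings$grid_shape,
                       seed = settings$seed)
  cohort <- make_cohort(cspec, atlas)
  cv <- run_cv(cohort$volumes, cohort$subjects, k = settings$k,
               spec = settings$arch,
               config = train_config(seed = settings$seed),
               seed = settings$seed)
  subjects <- cv$subjects
  accuracy <- mean(subjects$predicted_class == subjects$true_class)
  # raw maps keep per-subject evidence magnitude (used for clinical
  # association); mean-1 normalized maps put subjects on a common scale
  # (used for profiles and cross-area correlation structure)
  raw_maps <- holdout_maps(cv$models, subjects, cohort$volumes,
                           normalize = FALSE)
  norm_maps <- lapply(raw_maps, normalize_map)
  regional_raw <- regional_matrix(raw_maps, atlas)
  regional <- regional_matrix(norm_maps, atlas)
  eff <- cohort$effect_areas
  planted_network <- split_networks(atlas$labels$networks)[[eff[1]]][1]

  prof <- class_profiles(regional, subjects)
  pd_mean <- prof$mean[prof$class == "PD"]
  cutoff <- ceiling(0.2 * length(pd_mean))
  top <- order(pd_mean, decreasing = TRUE)[seq_len(cutoff)]
  effect_in_top20 <- all(eff %in% top)

  assoc <- metric_association(regional_raw, subjects, "updrs_p3")
  pooled <- cbind(effect_pooled = rowMeans(regional_raw[, eff, drop = FALSE]))
  assoc_pooled <- metric_association(pooled, subjects, "updrs_p3")
  assoc_positive_significant <- assoc_pooled$pearson_r > 0 &
    assoc_pooled$pearson_significant

  keep <- exclude_misclassified(subjects)$keep
  ct <- pairwise_kendall(regional[keep & subjects$true_class == "PD", ,
                                  drop = FALSE])
  contrast <- network_contrast(ct, atlas$labels$networks)
  crow <- contrast[contrast$network == planted_network, ]
  network_contrast_ok <- crow$intra_mean > crow$all_mean

  list(atlas = atlas, cohort = cohort, cv = cv, subjects = subjects,
       maps = norm_maps, regional = regional, regional_raw = regional_raw,
       profiles = prof, assoc = assoc, assoc_pooled = assoc_pooled,
       cortab = ct, contrast = contrast,
       planted_network = planted_network, effect_areas = eff,
       criteria = list(accuracy = accuracy,
                       effect_in_top20 = effect_in_top20,
                       assoc_positive_significant = assoc_positive_significant,
                       network_contrast_ok = network_contrast_ok))
}

#' Paint per-area statistics into a volume
#'
#' Writes each area's coefficient into its probability support (probability-
#' weighted, renormalized per voxel over the areas present) for visual parity
#' with surface/slice statistic maps.
#'
#' @param values named numeric vector, one value per area (atlas order).
#' @param atlas a `voxsal_atlas`.
#' @return 3D array on the atlas grid (0 outside all supports).
#' @export
stat_volume <- function(values, atlas) {
  P <- atlas_prob_matrix(atlas)
  stopifnot(length(values) == ncol(P))
  v <- ifelse(is.na(values), 0, values)
  num <- as.numeric(P %*% v)
  den <- rowSums(P)
  out <- ifelse(den > 0, num / den, 0)
  dim(out) <- atlas$grid_shape
  out
}
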