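#' Specify a synthetic cohort
#'
#' Encodes the generative assumptions the downstream analysis relies on:
#' per-subject latent severity (log-normal, median 1, right-skewed),
#' network-coupled effect factors, class-dependent regional intensity
#' reduction weighted by the atlas probability fields, heterogeneous scan
#' blur and noise, and clinical scores linearly coupled to severity.
#'
#' @param n_per_class subjects per class (PD and CT).
#' @param grid_shape voxel triple of each volume.
#' @param effect_areas integer indices (1-based atlas positions) of areas
#'   carrying the planted effect, or `NULL` to use every area of the first
#'   network.
#' @param effect_size delta, intensity units removed per unit severity.
#' @param severity_meanlog,severity_sdlog log-normal parameters of the latent
#'   severity s_i.
#' @param network_factor_sd sd of the per-subject per-network latent factor.
#' @param area_noise_sd sd of the per-subject per-area effect jitter.
#' @param blur_sd_range,noise_amp_range scan-quality heterogeneity: blur sd ~
#'   U(range) voxels, per-volume noise amplitude ~ U(range) intensity units
#'   (each voxel then adds U(0, amplitude)).
#' @param template_range intensity range of the shared template. Preprocessed
#'   MRI is intensity-normalized (the bulk of tissue sits near one level), so
#'   the default keeps template contrast moderate relative to \[0, 255\].
#' @param texture_sd amplitude of the subject-specific smooth texture field.
#' @param clinical_coeffs named list: `alpha_updrs`, `alpha_moca`,
#'   `moca_ceiling`, `updrs_noise_sd`, `moca_noise_sd`.
#' @param med_fraction fraction of PD subjects on medication.
#' @param clin_missing_frac fraction of PD clinical scores set missing.
#' @param seed RNG seed.
#' @return A `voxsal_cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 100L,
                        grid_shape = c(32L, 32L, 32L),
                        effect_areas = NULL,
                        effect_size = 30,
                        severity_meanlog = 0,
                        severity_sdlog = 0.5,
                        network_factor_sd = 0.3,
                        area_noise_sd = 0.1,
                        blur_sd_range = c(0, 1.5),
                        noise_amp_range = c(2, 8),
                        template_range = c(130, 190),
                        texture_sd = 4,
                        clinical_coeffs = list(alpha_updrs = 20,
                                               alpha_moca = 2,
                                               moca_ceiling = 28,
                                               updrs_noise_sd = 5,
                                               moca_noise_sd = 1.5),
                        med_fraction = 0.36,
                        clin_missing_frac = 0.1,
                        seed = 1L) {
  stopifnot(n_per_class >= 1, effect_size >= 0,
            blur_sd_range[1] <= blur_sd_range[2],
            noise_amp_range[1] <= noise_amp_range[2],
            med_fraction >= 0, med_fraction <= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 grid_shape = as.integer(grid_shape),
                 effect_areas = effect_areas,
                 effect_size = effect_size,
                 severity_meanlog = severity_meanlog,
                 severity_sdlog = severity_sdlog,
                 network_factor_sd = network_factor_sd,
                 area_noise_sd = area_noise_sd,
                 blur_sd_range = blur_sd_range,
                 noise_amp_range = noise_amp_range,
                 template_range = template_range,
                 texture_sd = texture_sd,
                 clinical_coeffs = clinical_coeffs,
                 med_fraction = med_fraction,
                 clin_missing_frac = clin_missing_frac,
                 seed = as.integer(seed)),
            class = "voxsal_cohort_spec")
}

smooth_field <- function(grid_shape, sd) {
  v <- array(runif(prod(grid_shape)), grid_shape)
  cpp_gauss_blur3(v, grid_shape, sd, 16L)
}

#' Generate a synthetic cohort of volumes and subject records
#'
#' A shared smooth template plus subject-specific smooth texture forms each
#' base volume. For PD subjects, intensity inside each effect area `a` is
#' reduced by `delta * (s_i + f_{i,net(a)} + eps_{i,a})` weighted by the
#' area's probability field, where `s_i` is the latent severity, `f` the
#' per-network factor and `eps` per-area jitter. Every volume (both classes)
#' is then blurred with a uniformly drawn sd, gets additive uniform noise
#' with a uniformly drawn amplitude, and is clamped to \[0, 255\]. Clinical
#' scores exist for PD subjects only: UPDRS P3 rises linearly with severity
#' (floored at 0), MoCA falls from its ceiling (clamped to \[0, 30\]), LEDD
#' exists for medicated subjects, and years-since-onset grows with severity.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a [make_atlas()] atlas on the same grid.
#' @return list with `subjects` (data.frame of subject records), `volumes`
#'   (list of 3D arrays), `effects` (PD-subject x effect-area matrix of the
#'   internal effect terms), `effect_areas`, and `template`.
#' @export
make_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "voxsal_cohort_spec"),
            inherits(atlas, "voxsal_atlas"),
            identical(spec$grid_shape, atlas$grid_shape))
  n_areas <- dim(atlas$probs)[4]
  effect_areas <- spec$effect_areas
  if (is.null(effect_areas))
    effect_areas <- which(atlas$labels$networks ==
                            atlas$labels$networks[1])
  if (length(effect_areas) == 0 && spec$effect_size > 0)
    stop("effect_size > 0 requires non-empty effect_areas")
  if (length(effect_areas) > 0)
    stopifnot(all(effect_areas >= 1), all(effect_areas <= n_areas))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  template <- smooth_field(gs, min(gs) / 8)
  template <- spec$template_range[1] +
    diff(spec$template_range) * (template - min(template)) /
    max(max(template) - min(template), .Machine$double.eps)
  networks <- vapply(strsplit(atlas$labels$networks, ";"), `[`, character(1), 1)
  eff_net <- networks[effect_areas]
  all_nets <- unique(networks)
  n_pd <- spec$n_per_class
  n <- 2L * n_pd
  cls <- rep(c("PD", "CT"), each = n_pd)
  ids <- sprintf("S%03d", seq_len(n))
  cc <- spec$clinical_coeffs
  severity <- rep(0, n)
  effects <- matrix(0, n_pd, length(effect_areas),
                    dimnames = list(ids[seq_len(n_pd)],
                                    atlas$labels$name[effect_areas]))
  volumes <- vector("list", n)
  updrs <- moca <- ledd <- years <- rep(NA_real_, n)
  medicated <- rep(FALSE, n)
  handed <- character(n)
  for (i in seq_len(n)) {
    vol <- template + spec$texture_sd *
      (smooth_field(gs, 2) - 0.5) * 12   # zero-mean smooth texture
    if (cls[i] == "PD") {
      s <- rlnorm(1, spec$severity_meanlog, spec$severity_sdlog)
      severity[i] <- s
      f_net <- rnorm(length(all_nets), 0, spec$network_factor_sd)
      names(f_net) <- all_nets
      if (length(effect_areas) > 0 && spec$effect_size > 0) {
        eps <- rnorm(length(effect_areas), 0, spec$area_noise_sd)
        e <- s + f_net[eff_net] + eps
        effects[i, ] <- e
        for (j in seq_along(effect_areas))
          vol <- vol - spec$effect_size * e[j] *
            atlas$probs[, , , effect_areas[j]]
      }
      updrs[i] <- max(0, cc$alpha_updrs * s + rnorm(1, 0, cc$updrs_noise_sd))
      moca[i] <- min(30, max(0, cc$moca_ceiling - cc$alpha_moca * s -
                               rnorm(1, 0, cc$moca_noise_sd)))
      years[i] <- max(0.1, 2.3 * s + rnorm(1, 0, 0.8))
      medicated[i] <- runif(1) < spec$med_fraction
      if (medicated[i]) ledd[i] <- max(0, 250 + 200 * s + rnorm(1, 0, 60))
      if (runif(1) < spec$clin_missing_frac) updrs[i] <- NA_real_
      if (runif(1) < spec$clin_missing_frac) moca[i] <- NA_real_
    }
    handed[i] <- sample(c("R", "L"), 1, prob = c(0.9, 0.1))
    bsd <- runif(1, spec$blur_sd_range[1], spec$blur_sd_range[2])
    vol <- cpp_gauss_blur3(vol, gs, bsd, 8L)
    amp <- runif(1, spec$noise_amp_range[1], spec$noise_amp_range[2])
    vol <- vol + runif(length(vol), 0, amp)
    vol[vol < 0] <- 0
    vol[vol > 255] <- 255
    dim(vol) <- gs
    volumes[[i]] <- vol
  }
  subjects <- data.frame(id = ids, true_class = cls,
                         updrs_p3 = updrs, moca = moca, ledd = ledd,
                         years_onset = years, handedness = handed,
                         medicated = medicated, latent_severity = severity,
                         fold = NA_integer_,
                         predicted_class = NA_character_,
                         stringsAsFactors = FALSE)
  list(subjects = subjects, volumes = volumes, effects = effects,
       effect_areas = effect_areas, template = template)
}

#' Write/read a cohort as per-subject NIfTI volumes plus a subjects CSV
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort$subjects)))
    RNifti::writeNifti(cohort$volumes[[i]],
                       file.path(dir, paste0(cohort$subjects$id[i], ".nii.gz")))
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  volumes <- lapply(subjects$id, function(id) {
    img <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    array(as.numeric(img), dim(img))
  })
  list(subjects = subjects, volumes = volumes)
}
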