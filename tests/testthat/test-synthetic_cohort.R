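test_that("atlas invariants hold across seeds and sizes", {
  for (seed in 1:3) {
    atlas <- make_atlas(10, c(16, 16, 16), n_networks = 3, seed = seed)
    expect_silent(validate_atlas(atlas))
    vs <- apply(atlas$probs, 1:3, sum)
    expect_lte(max(vs), 1 + 1e-9)
    expect_true(all(atlas$probs >= 0 & atlas$probs <= 1))
    expect_setequal(atlas$labels$hemisphere, c("L", "R"))
  }
  # odd area count puts the leftover area on the midline
  atlas <- make_atlas(5, c(17, 16, 16), seed = 2)
  expect_equal(sum(atlas$labels$hemisphere == "midline"), 1)
})

test_that("a single area covering the grid peaks at probability 1", {
  atlas <- make_atlas(1, c(9, 9, 9), seed = 3)
  expect_equal(max(atlas$probs), 1)
})

test_that("atlas and cohort generation are deterministic in the seed", {
  a1 <- make_atlas(6, c(12, 12, 12), seed = 7)
  a2 <- make_atlas(6, c(12, 12, 12), seed = 7)
  expect_identical(a1, a2)
  spec <- cohort_spec(n_per_class = 3, grid_shape = c(12L, 12L, 12L),
                      seed = 7)
  c1 <- make_cohort(spec, a1)
  c2 <- make_cohort(spec, a2)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$volumes, c2$volumes)
  a3 <- make_atlas(6, c(12, 12, 12), seed = 8)
  expect_false(identical(a1$probs, a3$probs))
})

test_that("atlas placement errors when the grid cannot hold the areas", {
  expect_error(make_atlas(80, c(8, 8, 8), seed = 1, min_separation = 4),
               "too small")
})

test_that("zero effect size leaves classes indistinguishable inside effect areas", {
  atlas <- make_atlas(6, c(16, 16, 16), seed = 11)
  spec <- cohort_spec(n_per_class = 50, grid_shape = c(16L, 16L, 16L),
                      effect_areas = 1:3, effect_size = 0, seed = 11)
  coh <- make_cohort(spec, atlas)
  w <- rowSums(voxsal:::atlas_prob_matrix(atlas)[, 1:3])
  wm <- vapply(coh$volumes, function(v) sum(v * w) / sum(w), numeric(1))
  pd <- wm[coh$subjects$true_class == "PD"]
  ct <- wm[coh$subjects$true_class == "CT"]
  se <- sqrt(var(pd) / length(pd) + var(ct) / length(ct))
  expect_lt(abs(mean(pd) - mean(ct)), 2 * se)
})

test_that("planted intensity reduction matches the generator's own effect term", {
  # severity with mean 1 (meanlog = -sdlog^2/2); no blur, minimal noise and
  # texture so the weighted intensity difference isolates the effect term
  atlas <- make_atlas(6, c(16, 16, 16), seed = 5)
  sdlog <- 0.5
  spec <- cohort_spec(n_per_class = 100, grid_shape = c(16L, 16L, 16L),
                      effect_areas = 1:3, effect_size = 30,
                      severity_meanlog = -sdlog^2 / 2, severity_sdlog = sdlog,
                      blur_sd_range = c(0, 0), noise_amp_range = c(0, 0.1),
                      texture_sd = 0.5, seed = 5)
  coh <- make_cohort(spec, atlas)
  P <- voxsal:::atlas_prob_matrix(atlas)[, 1:3]
  w <- rowSums(P)
  wm <- vapply(coh$volumes, function(v) sum(v * w) / sum(w), numeric(1))
  pd <- coh$subjects$true_class == "PD"
  measured <- mean(wm[pd]) - mean(wm[!pd])
  # Monte-Carlo expectation from the generator's internal effect matrix:
  # per-area overlap of the probability field with the support weights
  overlap <- colSums(P * w) / sum(w)
  oracle <- -spec$effect_size * mean(coh$effects %*% overlap)
  expect_lt(abs(measured - oracle), 0.1 * abs(oracle))
})

test_that("clinical scores are coupled to latent severity as planted", {
  atlas <- make_atlas(4, c(12, 12, 12), seed = 9)
  spec <- cohort_spec(n_per_class = 120, grid_shape = c(12L, 12L, 12L),
                      effect_areas = 1:2, clin_missing_frac = 0, seed = 9)
  coh <- make_cohort(spec, atlas)
  pd <- coh$subjects[coh$subjects$true_class == "PD", ]
  ct_u <- cor.test(pd$latent_severity, pd$updrs_p3)
  expect_gt(ct_u$estimate, 0)
  expect_lt(ct_u$p.value, 0.01)
  ct_m <- cor.test(pd$latent_severity, pd$moca)
  expect_lt(ct_m$estimate, 0)
  expect_lt(ct_m$p.value, 0.01)
})

test_that("control subjects carry no clinical scores and the record schema holds", {
  atlas <- make_atlas(4, c(12, 12, 12), seed = 13)
  coh <- make_cohort(cohort_spec(n_per_class = 10,
                                 grid_shape = c(12L, 12L, 12L), seed = 13),
                     atlas)
  ct <- coh$subjects[coh$subjects$true_class == "CT", ]
  expect_true(all(is.na(ct$updrs_p3)))
  expect_true(all(is.na(ct$ledd)))
  expect_true(all(is.na(ct$years_onset)))
  pd <- coh$subjects[coh$subjects$true_class == "PD", ]
  expect_true(all(is.na(pd$ledd[!pd$medicated])))
  expect_true(all(vapply(coh$volumes, function(v)
    min(v) >= 0 && max(v) <= 255, logical(1))))
})

test_that("same-network areas share more effect variance than cross-network", {
  atlas <- make_atlas(8, c(16, 16, 16), n_networks = 2, seed = 17)
  spec <- cohort_spec(n_per_class = 120, grid_shape = c(16L, 16L, 16L),
                      effect_areas = 1:4, seed = 17)
  coh <- make_cohort(spec, atlas)
  nets <- atlas$labels$networks[1:4]
  cm <- cor(coh$effects)
  same <- c(); cross <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    if (nets[i] == nets[j]) same <- c(same, cm[i, j])
    else cross <- c(cross, cm[i, j])
  }
  expect_gt(mean(same), mean(cross))
})

test_that("empty effect areas with positive effect size is a configuration error", {
  atlas <- make_atlas(4, c(12, 12, 12), seed = 1)
  spec <- cohort_spec(n_per_class = 2, grid_shape = c(12L, 12L, 12L),
                      effect_areas = integer(0), effect_size = 10, seed = 1)
  expect_error(make_cohort(spec, atlas), "effect_areas")
})

test_that("atlas and cohort round-trip through NIfTI and CSV", {
  dir <- withr::local_tempdir()
  atlas <- make_atlas(4, c(12, 12, 12), seed = 21)
  write_atlas(atlas, file.path(dir, "atlas"))
  back <- read_atlas(file.path(dir, "atlas"))
  expect_equal(back$probs, atlas$probs, tolerance = 1e-6)
  expect_equal(back$labels$name, atlas$labels$name)
  coh <- make_cohort(cohort_spec(n_per_class = 2,
                                 grid_shape = c(12L, 12L, 12L), seed = 21),
                     atlas)
  write_cohort(coh, file.path(dir, "cohort"))
  back2 <- read_cohort(file.path(dir, "cohort"))
  expect_equal(back2$subjects$id, coh$subjects$id)
  expect_equal(back2$volumes[[1]], coh$volumes[[1]], tolerance = 1e-4)
})
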