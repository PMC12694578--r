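test_that("2D-to-3D inflation replicates depth slices and multiplies counts", {
  w11 <- array(rnorm(1 * 1 * 8 * 8), c(1, 1, 8, 8))
  expect_length(inflate_2d_to_3d(w11), 64)

  w33 <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  w3d <- inflate_2d_to_3d(w33)
  expect_length(w3d, 216)
  for (kd in 1:3) expect_identical(w3d[kd, , , , ], w33)

  w77 <- array(rnorm(7 * 7 * 1 * 64), c(7, 7, 1, 64))
  expect_length(inflate_2d_to_3d(w77), 21952)

  expect_equal(inflate_2d_to_3d(w33, scale = TRUE)[2, , , , ], w33 / 3)
  expect_error(inflate_2d_to_3d(array(0, c(3, 5, 1, 1))), "square")
})

test_that("parameter count matches a hand enumeration on a minimal spec", {
  spec <- architecture_spec(in_channels = 1L, stem_channels = 2L,
                            stem_kernel = 3L, stem_pool = FALSE,
                            stages = list(c(1L, 2L)), dropout = 0)
  m <- build_model(spec)
  # stem conv 27*1*2 + stem bn 2*2 + block conv1 27*2*2 + bn 4 +
  # conv2 27*2*2 + bn 4 + fc 2*2 weights + 2 biases
  expect_equal(count_parameters(m), 54 + 4 + 108 + 4 + 108 + 4 + 6)
})

test_that("parameter count is invariant to initialization mode", {
  spec <- architecture_spec(stem_channels = 2L, stem_kernel = 3L,
                            stages = list(c(1L, 2L)))
  set.seed(1)
  w2d <- list(array(rnorm(9 * 2), c(3, 3, 1, 2)),
              array(rnorm(9 * 4), c(3, 3, 2, 2)),
              array(rnorm(9 * 4), c(3, 3, 2, 2)))
  m_glorot <- build_model(spec)
  m_infl <- build_model(spec, init = "inflated-from-2d", weights2d = w2d)
  expect_equal(count_parameters(m_glorot), count_parameters(m_infl))
  # inflated stem really is the replicated 2D kernel
  for (kd in 1:3)
    expect_equal(as.numeric(m_infl$stem$W[kd, , , , ]),
                 as.numeric(w2d[[1]]))
})

test_that("learnable layer count follows the residual counting convention", {
  expect_equal(learnable_layers(architecture_spec()), 12)
  expect_equal(learnable_layers(architecture_spec_18()), 18)
  expect_equal(learnable_layers(tiny_arch()), 4)
})

test_that("fold assignment partitions, stratifies and is seeded", {
  ids <- sprintf("S%03d", 1:200)
  cls <- rep(c("PD", "CT"), each = 100)
  fa <- assign_folds(ids, k = 4, seed = 3, classes = cls)
  expect_equal(sort(unname(table(fa$membership))), rep(50L, 4),
               ignore_attr = TRUE)
  for (f in 1:4)
    expect_equal(sum(cls == "PD" & fa$membership == f), 25)
  expect_identical(fa, assign_folds(ids, k = 4, seed = 3, classes = cls))
  expect_false(identical(fa$membership,
                         assign_folds(ids, k = 4, seed = 4,
                                      classes = cls)$membership))
  # leave-one-out limit and error cases
  loo <- assign_folds(letters[1:4], k = 4, seed = 1)
  expect_equal(sort(unname(loo$membership)), 1:4)
  expect_error(assign_folds(letters[1:3], k = 5, seed = 1), "more folds")
})

test_that("fold partition property holds under fuzzing", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    k <- sample(2:min(6, n), 1)
    ids <- sprintf("x%03d", seq_len(n))
    cls <- sample(c("PD", "CT"), n, replace = TRUE)
    fa <- assign_folds(ids, k = k, seed = rep, classes = cls)
    expect_setequal(names(fa$membership), ids)
    sizes <- table(factor(fa$membership, levels = seq_len(k)))
    expect_lte(max(sizes) - min(sizes), 1)
    for (f in seq_len(k)) {
      bal <- sum(cls == "PD" & fa$membership == f)
      expect_lte(abs(bal - sum(cls == "PD") / k), 1)
    }
  }
})

test_that("augmentation chain has the stated range and mean", {
  set.seed(1)
  v255 <- array(255, c(20, 20, 20))
  a <- augment_volume(v255)
  expect_gte(min(a), 249.9 - 1e-9)
  expect_lte(max(a), 254.9 + 1e-9)

  v100 <- array(100, c(102, 102, 102))  # > 1e6 voxels
  a100 <- augment_volume(v100)
  expect_lt(abs(mean(a100) - 100.5), 0.05)

  z <- augment_volume(array(0, c(16, 16, 16)))
  expect_gte(min(z), 0)
  expect_lte(max(z), 5)
})

test_that("training separates classes split by a constant intensity offset", {
  set.seed(5)
  mk <- function(level, n) lapply(seq_len(n), function(i)
    array(pmin(pmax(level + rnorm(16^3, 0, 2), 0), 255), c(16, 16, 16)))
  vols <- c(mk(60, 10), mk(160, 10))
  labs <- rep(c("CT", "PD"), each = 10)
  tr <- c(1:6, 11:16); te <- c(7:10, 17:20)
  fit <- train_fold(vols[tr], labs[tr], config = train_config(seed = 1),
                    spec = tiny_arch(4L))
  pr <- predict_model(fit$model, vols[te])
  expect_equal(mean(pr$predicted_class == labs[te]), 1)
  expect_length(fit$loss_trace, 20)
})

test_that("training is bit-deterministic in the seed and refuses one class", {
  set.seed(2)
  vols <- lapply(1:8, function(i) array(runif(8^3, 0, 255), c(8, 8, 8)))
  labs <- rep(c("PD", "CT"), 4)
  cfg <- train_config(seed = 11, epochs = 3)
  f1 <- train_fold(vols, labs, config = cfg, spec = tiny_arch())
  f2 <- train_fold(vols, labs, config = cfg, spec = tiny_arch())
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$model$fc$W, f2$model$fc$W)
  expect_error(train_fold(vols, rep("PD", 8), config = cfg,
                          spec = tiny_arch()), "single class")
})

test_that("no-signal cohorts stay at chance accuracy", {
  # pooled held-out accuracy over 5 seeded replicates of a zero-effect
  # cohort must sit inside the binomial chance band for 40 test subjects
  accs <- numeric(5)
  for (seed in 1:5) {
    atlas <- make_atlas(4, c(16, 16, 16), seed = seed)
    spec <- cohort_spec(n_per_class = 20, grid_shape = c(16L, 16L, 16L),
                        effect_areas = 1:2, effect_size = 0, seed = seed)
    coh <- make_cohort(spec, atlas)
    tr <- c(1:10, 21:30); te <- c(11:20, 31:40)
    fit <- train_fold(coh$volumes[tr], coh$subjects$true_class[tr],
                      config = train_config(seed = seed),
                      spec = tiny_arch(4L))
    pr <- predict_model(fit$model, coh$volumes[te])
    accs[seed] <- mean(pr$predicted_class == coh$subjects$true_class[te])
  }
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("evaluation metrics match the confusion-matrix arithmetic", {
  # 50-subject fold with TP=21 FP=7 FN=1 TN=21
  truth <- c(rep("PD", 22), rep("CT", 28))
  pred <- c(rep("PD", 21), "CT", rep("PD", 7), rep("CT", 21))
  e <- evaluate(truth, pred)
  expect_equal(e$accuracy, 0.84)
  expect_equal(e$precision, 0.75)
  expect_equal(e$recall, 0.9545, tolerance = 1e-4)
  expect_equal(e$f1, 0.8400, tolerance = 1e-4)

  all_right <- evaluate(c("PD", "CT"), c("PD", "CT"))
  expect_equal(unlist(all_right[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  e2 <- evaluate(rep(c("PD", "CT"), 5), rep("PD", 10))
  expect_equal(e2$recall, 1)
  expect_equal(e2$precision, 0.5)
  expect_equal(e2$f1, 2 / 3)
  expect_error(evaluate(character(0), character(0)), "empty")
})

test_that("cross-validation summary pools fold metrics with 95% half-widths", {
  subjects <- fake_subjects(rep(c("PD", "CT"), 20),
                            fold = rep(1:4, each = 10))
  subjects$predicted_class <- subjects$true_class
  subjects$predicted_class[c(1, 12)] <- c("CT", "PD")
  ev <- evaluate_cv(subjects)
  expect_equal(nrow(ev$per_fold), 4)
  acc <- ev$per_fold$accuracy
  pooled_acc <- ev$pooled[ev$pooled$metric == "accuracy", ]
  expect_equal(pooled_acc$mean, mean(acc))
  expect_equal(pooled_acc$half_width, 1.96 * sd(acc) / 2)
})

test_that("model checkpoints round-trip through JSON header plus payload", {
  dir <- withr::local_tempdir()
  model <- tiny_model(seed = 21, channels = 3L)
  set.seed(22)
  vols <- lapply(1:3, function(i) array(runif(8^3, 0, 255), c(8, 8, 8)))
  p1 <- predict_model(model, vols)
  save_model(model, file.path(dir, "ckpt"))
  back <- load_model(file.path(dir, "ckpt"))
  expect_identical(back$spec, model$spec)
  expect_equal(back$stem$W, model$stem$W)
  expect_equal(predict_model(back, vols), p1)
})
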