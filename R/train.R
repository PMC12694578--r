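#' Training configuration
#'
#' Defaults are the fixed hyperparameter set used throughout: ADAM, mini-batch
#' 10, 20 epochs, static learning rate 3e-4, L2 regularization 5e-4, data
#' shuffled each epoch, fully connected layer trained at 5x the base learning
#' rate, inputs rescaled from \[0, 255\] to \[0, 1\].
#'
#' @param minibatch,epochs,learning_rate,l2 optimizer settings.
#' @param shuffle_each_epoch reshuffle the training order every epoch.
#' @param fc_lr_multiplier learning-rate scalar of the fully connected layer.
#' @param augment apply the harmonization augmentation chain each epoch.
#' @param augment_reps number of independent augmentation draws per volume per
#'   epoch (each producing one training sample).
#' @param seed RNG seed controlling initialization, shuffling, dropout and
#'   augmentation draws.
#' @export
train_config <- function(minibatch = 10L, epochs = 20L, learning_rate = 3e-4,
                         l2 = 5e-4, shuffle_each_epoch = TRUE,
                         fc_lr_multiplier = 5, augment = TRUE,
                         augment_reps = 1L, seed = 1L) {
  stopifnot(minibatch >= 1, epochs >= 1, learning_rate > 0, l2 >= 0,
            fc_lr_multiplier > 0, augment_reps >= 1)
  structure(list(minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, l2 = l2,
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 fc_lr_multiplier = fc_lr_multiplier,
                 augment = isTRUE(augment),
                 augment_reps = as.integer(augment_reps),
                 seed = as.integer(seed)),
            class = "voxsal_train_config")
}

#' Assign subjects to cross-validation folds
#'
#' Folds partition the subjects into near-equal groups (sizes differ by at
#' most one). When class labels are supplied the assignment is stratified so
#' each fold's class balance matches the cohort's within one subject.
#'
#' @param subject_ids character vector of unique ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param classes optional class label per subject for stratification.
#' @return A list with `k` and `membership` (named integer vector, fold index
#'   per subject).
#' @export
assign_folds <- function(subject_ids, k = 4L, seed = 1L, classes = NULL) {
  n <- length(subject_ids)
  stopifnot(k >= 2, !anyDuplicated(subject_ids))
  if (k > n) stop("more folds than subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  membership <- integer(n)
  names(membership) <- subject_ids
  if (is.null(classes)) {
    membership[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    stopifnot(length(classes) == n)
    # deal fold indices within each class separately, rotating the starting
    # fold so overall fold sizes stay within one of each other
    offset <- 0L
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      folds <- (offset + seq_along(idx) - 1L) %% k + 1L
      membership[idx[sample.int(length(idx))]] <- folds
      offset <- (offset + length(idx)) %% k
    }
  }
  list(k = as.integer(k), membership = membership)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Harmonization augmentation for one volume
#'
#' Gaussian blur with a standard deviation drawn uniformly from \[0, 1.5\]
#' voxels (separable kernel truncated to a 16-voxel-wide window), followed by
#' a 2 percent overall intensity drop, then an additive per-voxel noise mask
#' drawn uniformly from \[0, 5\]. Intensities are expected in \[0, 255\] and
#' remain there (0.98 * 255 + 5 < 255).
#'
#' @param vol 3D numeric array with intensities in \[0, 255\].
#' @return augmented array of the same shape.
#' @export
augment_volume <- function(vol) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  sdv <- runif(1, 0, 1.5)
  v <- cpp_gauss_blur3(vol, d, sdv, 8L)
  v <- v * 0.98 + runif(length(v), 0, 5)
  v[v < 0] <- 0
  v[v > 255] <- 255
  dim(v) <- d
  v
}

stack_volumes <- function(volumes) {
  d <- dim(volumes[[1]])
  x <- array(0, c(d, 1L, length(volumes)))
  for (i in seq_along(volumes)) x[, , , 1L, i] <- volumes[[i]]
  x
}

adam_init <- function(model) {
  tab <- param_table(model)
  lapply(tab, function(e) {
    v <- get_path(model, e$path)
    list(m = v * 0, v = v * 0)
  })
}

adam_step <- function(model, grads, state, config, t) {
  tab <- param_table(model)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(tab)) {
    e <- tab[[i]]
    th <- get_path(model, e$path)
    g <- get_path(grads, e$path)
    if (e$decay && config$l2 > 0) g <- g + config$l2 * th
    st <- state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    th <- th - config$learning_rate * e$lr_mult * mhat / (sqrt(vhat) + eps)
    model <- set_path(model, e$path, th)
    state[[i]] <- st
  }
  list(model = model, state = state)
}

class_levels <- function() c("CT", "PD")

#' Train one cross-validation fold
#'
#' Minimizes softmax cross-entropy with ADAM at the configured
#' hyperparameters; the fully connected layer uses `fc_lr_multiplier` times
#' the base learning rate. When `config$augment` is set, the augmentation
#' chain of [augment_volume()] is re-drawn for every volume every epoch.
#' All randomness comes from `config$seed`, so repeated runs on one machine
#' give bit-identical loss traces.
#'
#' @param volumes list of 3D arrays with intensities in \[0, 255\].
#' @param labels character/factor labels ("PD"/"CT"), one per volume.
#' @param config a [train_config()].
#' @param spec a [architecture_spec()].
#' @return list with the trained `model` and the per-epoch `loss_trace`.
#' @export
train_fold <- function(volumes, labels, config = train_config(),
                       spec = architecture_spec()) {
  labels <- as.character(labels)
  stopifnot(length(volumes) == length(labels))
  if (length(unique(labels)) < 2)
    stop("training set contains a single class; need both PD and CT")
  if (!all(labels %in% class_levels()))
    stop("labels must be 'PD' or 'CT'")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  model <- build_model(spec)
  state <- adam_init(model)
  yidx <- match(labels, class_levels())
  n <- length(volumes)
  loss_trace <- numeric(config$epochs)
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (config$augment) {
      xs <- list(); ys <- integer(0)
      for (r in seq_len(config$augment_reps)) {
        xs <- c(xs, lapply(volumes, augment_volume))
        ys <- c(ys, yidx)
      }
    } else {
      xs <- volumes; ys <- yidx
    }
    ord <- if (config$shuffle_each_epoch) sample.int(length(xs)) else
      seq_along(xs)
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = config$minibatch)) {
      sel <- ord[start:min(start + config$minibatch - 1L, length(ord))]
      xb <- stack_volumes(xs[sel]) / 255
      fw <- net_forward(model, xb, training = TRUE)
      model <- fw$model
      ls <- softmax_xent(fw$scores, ys[sel])
      grads <- net_backward(model, fw$caches, ls$grad)
      t <- t + 1L
      up <- adam_step(model, grads, state, config, t)
      model <- up$model
      state <- up$state
      losses <- c(losses, ls$loss)
    }
    loss_trace[epoch] <- mean(losses)
  }
  model <- calibrate_bn(model, volumes)
  list(model = model, loss_trace = loss_trace)
}

# Replace the EMA batch-norm running moments with exact population moments of
# the clean (non-augmented) training volumes under the trained weights:
# one full-set forward pass with batch statistics, dropout off, and momentum
# 1 so each layer's running moments become that pass's exact moments. Small
# mini-batches plus augmented-vs-clean input shift otherwise leave
# evaluation-mode normalization systematically offset from the statistics
# prediction inputs actually have.
calibrate_bn <- function(model, volumes) {
  set_all <- function(m, field, value) {
    m$stem_bn[[field]] <- value
    for (i in seq_along(m$blocks)) {
      for (nm in c("bn1", "bn2", "proj_bn"))
        if (!is.null(m$blocks[[i]][[nm]]))
          m$blocks[[i]][[nm]][[field]] <- value
    }
    m
  }
  momenta <- model$stem_bn$momentum
  drop_p <- model$dropout_p
  model <- set_all(model, "momentum", 1)
  model$dropout_p <- 0
  x <- stack_volumes(volumes) / 255
  fw <- net_forward(model, x, training = TRUE)
  model <- fw$model
  model <- set_all(model, "momentum", momenta)
  model$dropout_p <- drop_p
  model
}

#' Predict class labels for volumes
#'
#' Deterministic evaluation-mode forward pass (dropout off, running
#' batch-norm moments).
#' @param model trained `voxsal_model`.
#' @param volumes list of 3D arrays in \[0, 255\].
#' @return data.frame with class scores and `predicted_class`.
#' @export
predict_model <- function(model, volumes) {
  x <- stack_volumes(volumes) / 255
  fw <- net_forward(model, x, training = FALSE)
  sc <- fw$scores
  colnames(sc) <- paste0("score_", class_levels())
  data.frame(sc,
             predicted_class = class_levels()[max.col(sc, ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Run seeded stratified k-fold training over a cohort
#'
#' Trains one model per fold on the out-of-fold subjects and predicts the
#' held-out subjects, so every subject is tested exactly once.
#'
#' @param volumes list of 3D arrays in \[0, 255\].
#' @param subjects data.frame with at least `id` and `true_class` columns.
#' @param k number of folds.
#' @param spec architecture to train.
#' @param config base [train_config()]; each fold trains with seed
#'   `config$seed * 100 + fold`.
#' @param seed seed for the fold assignment.
#' @return list with `models` (per fold), `folds`, and `subjects` with
#'   `fold` and `predicted_class` filled in.
#' @export
run_cv <- function(volumes, subjects, k = 4L, spec = architecture_spec(),
                   config = train_config(), seed = 1L) {
  stopifnot(nrow(subjects) == length(volumes))
  folds <- assign_folds(subjects$id, k = k, seed = seed,
                        classes = subjects$true_class)
  subjects$fold <- unname(folds$membership[subjects$id])
  models <- vector("list", k)
  subjects$predicted_class <- NA_character_
  subjects$score_CT <- NA_real_
  subjects$score_PD <- NA_real_
  for (f in seq_len(k)) {
    test_idx <- which(subjects$fold == f)
    train_idx <- setdiff(seq_len(nrow(subjects)), test_idx)
    cfg <- config
    cfg$seed <- config$seed * 100L + f
    fit <- train_fold(volumes[train_idx], subjects$true_class[train_idx],
                      config = cfg, spec = spec)
    models[[f]] <- fit$model
    pr <- predict_model(fit$model, volumes[test_idx])
    subjects$predicted_class[test_idx] <- pr$predicted_class
    subjects$score_CT[test_idx] <- pr$score_CT
    subjects$score_PD[test_idx] <- pr$score_PD
  }
  list(models = models, folds = folds, subjects = subjects)
}
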