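#' Gradient-weighted class activation map for one volume
#'
#' Runs a deterministic evaluation-mode forward pass, backpropagates the
#' selected class's pre-softmax score to the designated layer (the output of
#' the final residual stage, before dropout and pooling), spatially averages
#' the gradient into one weight per channel, forms the half-rectified
#' weighted sum of the feature maps, and trilinearly upsamples it
#' (corner-aligned) to the input grid. With `grad_target = "loss"` the
#' negative log-likelihood of the selected class is backpropagated instead of
#' its score.
#'
#' @param model trained `voxsal_model`.
#' @param volume 3D array in \[0, 255\] matching the model input shape.
#' @param class_channel `"PD"` or `"CT"`.
#' @param grad_target gradient source: pre-softmax class `"score"` (default)
#'   or cross-entropy `"loss"`.
#' @return A saliency map object (class `voxsal_saliency`): non-negative
#'   `values` on the input grid, `channel_weights`, the feature-grid shape,
#'   and provenance fields (`subject_id`, `fold`, `class_channel`).
#' @export
gradcam <- function(model, volume, class_channel = c("PD", "CT"),
                    grad_target = c("score", "loss")) {
  class_channel <- match.arg(class_channel)
  grad_target <- match.arg(grad_target)
  d <- dim(volume)
  stopifnot(length(d) == 3)
  x <- array(volume / 255, c(d, 1L, 1L))
  fw <- net_forward(model, x, training = FALSE)
  A <- fw$caches$features
  fd <- dim(A)
  S <- prod(fd[1:3])
  C <- fd[4]
  h <- match(class_channel, class_levels())
  # backpropagate the gradient target through the head (dropout is identity
  # in eval mode) to the designated layer
  gscores <- matrix(0, 1, length(class_levels()))
  if (grad_target == "score") {
    gscores[1, h] <- 1
  } else {
    p <- exp(fw$scores - max(fw$scores))
    p <- p / sum(p)
    gscores[1, ] <- p
    gscores[1, h] <- gscores[1, h] - 1
  }
  fb <- fc_bwd(model$fc, fw$caches$gap$G, gscores)
  gA <- gap_bwd(fb$gG, fw$caches$gap)
  if (!all(is.finite(gA))) stop("non-finite gradients at the designated layer")
  # Channel weights: spatial mean of the gradient (Grad-CAM normalization by
  # the feature-map voxel count).
  w <- channel_sums(as.numeric(gA), S, C, 1L) / S
  Af <- matrix(A, nrow = S)
  m <- pmax(Af %*% w, 0)
  dim(m) <- fd[1:3]
  # upsample respecting the network geometry: feature voxel i sits at input
  # voxel stride_total * i (centered odd kernels with same-padding), so the
  # map is stretched by the cumulative stride, not corner-aligned
  values <- cpp_upsample3_stride(m, fd[1:3], d, model_stride(model))
  structure(list(values = values, channel_weights = as.numeric(w),
                 feature_grid = fd[1:3], subject_id = NA_character_,
                 fold = NA_integer_, class_channel = class_channel,
                 normalized = FALSE, all_zero = all(m == 0)),
            class = "voxsal_saliency")
}

#' Normalize a saliency map to unit mean over a mask
#'
#' Group comparisons use maps divided by their own mean over the brain mask,
#' so every subject contributes on a common scale (regional means then sit
#' near 1). An all-zero map is returned unchanged with a warning flag.
#'
#' @param map a `voxsal_saliency`.
#' @param mask logical array on the same grid, or `NULL` for all voxels.
#' @return the map with `values` rescaled and `normalized = TRUE`.
#' @export
normalize_map <- function(map, mask = NULL) {
  stopifnot(inherits(map, "voxsal_saliency"))
  if (is.null(mask)) mask <- array(TRUE, dim(map$values))
  stopifnot(identical(dim(mask), dim(map$values)))
  mu <- mean(map$values[mask])
  if (mu <= 0) {
    warning("all-zero saliency map; returned unnormalized")
    map$all_zero <- TRUE
    return(map)
  }
  map$values <- map$values / mu
  map$normalized <- TRUE
  map
}

#' Hold-out saliency maps for a cohort
#'
#' Each subject's map is computed by the model of the fold where that subject
#' was held out, on the channel of the subject's *predicted* class (so
#' misclassified subjects yield maps of the wrong class, which the exclusion
#' rule later removes).
#'
#' @param models list of trained models, one per fold.
#' @param subjects data.frame with `id`, `fold`, `predicted_class` filled in.
#' @param volumes list of 3D arrays, same order as `subjects`.
#' @param normalize divide each map by its mean over `mask`.
#' @param mask optional logical array for normalization.
#' @return list of `voxsal_saliency`, one per subject, in cohort order.
#' @export
holdout_maps <- function(models, subjects, volumes, normalize = TRUE,
                         mask = NULL) {
  stopifnot(nrow(subjects) == length(volumes),
            !anyNA(subjects$fold), !anyNA(subjects$predicted_class))
  if (max(subjects$fold) > length(models) ||
      any(vapply(models[unique(subjects$fold)], is.null, logical(1))))
    stop("missing fold model")
  maps <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    mp <- gradcam(models[[subjects$fold[i]]], volumes[[i]],
                  class_channel = subjects$predicted_class[i])
    mp$subject_id <- subjects$id[i]
    mp$fold <- subjects$fold[i]
    if (normalize) mp <- normalize_map(mp, mask)
    maps[[i]] <- mp
  }
  maps
}
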