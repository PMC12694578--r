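#' Generate a synthetic probabilistic atlas
#'
#' Areas are isotropic Gaussian probability blobs placed as mirrored
#' left/right pairs about the mid-sagittal plane (an odd leftover area sits on
#' the midline), so every lobe has homologous areas in both hemispheres, as a
#' bilateral brain parcellation does. Where the stacked per-voxel probability
#' sum exceeds one, all areas at that voxel are renormalized by the sum.
#' Hemisphere is assigned from the x coordinate of each blob center; lobes are
#' assigned round-robin over mirrored pairs and networks round-robin over
#' areas (networks therefore span hemispheres and lobes).
#'
#' @param n_areas number of areas (>= 2 except for degenerate test use).
#' @param grid_shape integer triple of voxel dimensions.
#' @param n_networks number of functional-network labels.
#' @param seed RNG seed; the atlas is a pure function of the arguments.
#' @param n_lobes number of lobe labels.
#' @param sigma_range range of blob standard deviations in voxels (default
#'   scales with the grid).
#' @param min_separation minimum center-to-center distance in voxels.
#' @return A `voxsal_atlas`: `grid_shape`, `probs` (4D array, area axis
#'   last), and `labels` (data.frame with index, name, hemisphere, lobe,
#'   networks).
#' @export
make_atlas <- function(n_areas, grid_shape, n_networks = 4L, seed = 1L,
                       n_lobes = 4L, sigma_range = NULL,
                       min_separation = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(n_areas >= 1, length(grid_shape) == 3, all(grid_shape >= 3))
  if (is.null(sigma_range))
    sigma_range <- c(min(grid_shape) / 16, min(grid_shape) / 10)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- grid_shape[1]
  margin <- max(2, round(min(grid_shape) * 0.12))
  n_pairs <- n_areas %/% 2L
  n_mid <- n_areas %% 2L
  mid_x <- (D + 1) / 2
  if (margin + 1 > mid_x - min_separation / 2 ||
      margin + 1 > grid_shape[2] - margin ||
      margin + 1 > grid_shape[3] - margin)
    stop("grid too small to place ", n_areas, " distinct area centers")
  # sample left-hemisphere centers, mirror to the right
  centers <- matrix(NA_real_, n_areas, 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * max(1L, n_areas)
  while (placed < n_pairs && tries < max_tries) {
    tries <- tries + 1L
    cand <- round(c(runif(1, margin + 1, mid_x - min_separation / 2),
                    runif(1, margin + 1, grid_shape[2] - margin),
                    runif(1, margin + 1, grid_shape[3] - margin)))
    both <- rbind(cand, c(2 * mid_x - cand[1], cand[2], cand[3]))
    ok <- TRUE
    if (placed > 0) {
      prev <- centers[seq_len(2L * placed), , drop = FALSE]
      for (r in 1:2) {
        dist <- sqrt(rowSums((prev - matrix(both[r, ], nrow(prev), 3,
                                            byrow = TRUE))^2))
        if (any(dist < min_separation)) ok <- FALSE
      }
    }
    if (ok) {
      centers[2L * placed + 1L, ] <- both[1, ]
      centers[2L * placed + 2L, ] <- both[2, ]
      placed <- placed + 1L
    }
  }
  if (placed < n_pairs)
    stop("grid too small to place ", n_areas, " distinct area centers")
  if (n_mid == 1L) {
    for (t in seq_len(max_tries)) {
      cand <- c(mid_x, round(runif(1, margin + 1, grid_shape[2] - margin)),
                round(runif(1, margin + 1, grid_shape[3] - margin)))
      if (n_pairs == 0) { centers[n_areas, ] <- cand; break }
      prev <- centers[seq_len(2L * n_pairs), , drop = FALSE]
      dist <- sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                          byrow = TRUE))^2))
      if (all(dist >= min_separation)) { centers[n_areas, ] <- cand; break }
      if (t == max_tries)
        stop("grid too small to place the midline area center")
    }
  }
  sigmas <- runif(n_areas, sigma_range[1], sigma_range[2])
  # mirrored pairs share a width so homologues match
  if (n_pairs > 0) {
    pair_idx <- rep(seq_len(n_pairs), each = 2)
    sigmas[seq_len(2 * n_pairs)] <- sigmas[2 * pair_idx - 1]
  }
  gx <- seq_len(grid_shape[1]); gy <- seq_len(grid_shape[2])
  gz <- seq_len(grid_shape[3])
  probs <- array(0, c(grid_shape, n_areas))
  for (a in seq_len(n_areas)) {
    dx2 <- (gx - centers[a, 1])^2
    dy2 <- (gy - centers[a, 2])^2
    dz2 <- (gz - centers[a, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    probs[, , , a] <- exp(-d2 / (2 * sigmas[a]^2))
  }
  vox_sum <- apply(probs, 1:3, sum)
  scale <- ifelse(vox_sum > 1, 1 / vox_sum, 1)
  for (a in seq_len(n_areas)) probs[, , , a] <- probs[, , , a] * scale
  hemi <- ifelse(abs(centers[, 1] - mid_x) < 1e-9, "midline",
                 ifelse(centers[, 1] < mid_x, "L", "R"))
  lobe_of_pair <- paste0("lobe", (seq_len(max(1L, n_pairs + n_mid)) - 1L) %%
                           n_lobes + 1L)
  lobe <- character(n_areas)
  if (n_pairs > 0)
    lobe[seq_len(2 * n_pairs)] <- rep(lobe_of_pair[seq_len(n_pairs)], each = 2)
  if (n_mid == 1L) lobe[n_areas] <- lobe_of_pair[n_pairs + 1L]
  networks <- paste0("net", (seq_len(n_areas) - 1L) %% n_networks + 1L)
  labels <- data.frame(index = seq_len(n_areas) - 1L,
                       name = sprintf("area%03d_%s", seq_len(n_areas), hemi),
                       hemisphere = hemi, lobe = lobe, networks = networks,
                       stringsAsFactors = FALSE)
  structure(list(grid_shape = grid_shape, probs = probs, labels = labels,
                 centers = centers, sigmas = sigmas),
            class = "voxsal_atlas")
}

#' Validate probabilistic-atlas invariants
#'
#' Checks that every probability lies in \[0, 1\], per-voxel sums over areas
#' do not exceed 1 (+1e-9), every area has strictly positive total mass, and
#' label indices are unique and contiguous from 0.
#' @param atlas a `voxsal_atlas`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "voxsal_atlas"))
  p <- atlas$probs
  if (any(p < 0) || any(p > 1)) stop("probabilities outside [0,1]")
  n_areas <- dim(p)[4]
  vs <- apply(p, 1:3, sum)
  if (any(vs > 1 + 1e-9)) stop("per-voxel probability sum exceeds 1")
  mass <- apply(p, 4, sum)
  if (any(mass <= 0)) stop("area with zero probability mass")
  if (!identical(sort(atlas$labels$index), 0:(n_areas - 1L)))
    stop("label indices not unique/contiguous from 0")
  invisible(TRUE)
}

atlas_prob_matrix <- function(atlas) {
  matrix(atlas$probs, nrow = prod(atlas$grid_shape))
}

#' Write/read an atlas as 4D NIfTI plus a labels TSV
#'
#' The probability stack is written with the area axis last; the labels table
#' has columns index, name, hemisphere, lobe, networks (semicolon-separated
#' list).
#' @param atlas a `voxsal_atlas`.
#' @param path file stem; writes `<path>.nii.gz` and `<path>_labels.tsv`.
#' @return invisibly the two file paths.
#' @export
write_atlas <- function(atlas, path) {
  nii <- paste0(path, ".nii.gz")
  tsv <- paste0(path, "_labels.tsv")
  RNifti::writeNifti(atlas$probs, nii)
  write.table(atlas$labels, tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(nii, tsv))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  probs <- array(as.numeric(img), dim(img))
  labels <- read.delim(paste0(path, "_labels.tsv"),
                       stringsAsFactors = FALSE)
  atlas <- structure(list(grid_shape = dim(probs)[1:3], probs = probs,
                          labels = labels),
                     class = "voxsal_atlas")
  validate_atlas(atlas)
  atlas
}
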