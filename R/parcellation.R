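#' Probability-weighted regional saliency scores for one map
#'
#' For every atlas area `a`, `score_a = sum_v p_a(v) M(v) / sum_v p_a(v)`:
#' the saliency average weighted by the area's probability field. The
#' denominator is the area's total probability mass, so a constant map scores
#' that constant in every area. Areas are scored independently; overlapping
#' probability support is allowed.
#'
#' @param map a `voxsal_saliency` (or bare 3D array).
#' @param atlas a `voxsal_atlas` on the same grid.
#' @return named numeric vector, one score per area (NA with a warning for
#'   areas with zero mass).
#' @export
regional_scores <- function(map, atlas) {
  m <- if (inherits(map, "voxsal_saliency")) map$values else map
  if (!identical(dim(m), as.integer(atlas$grid_shape)) &&
      !identical(dim(m), atlas$grid_shape))
    stop("saliency map and atlas are on different grids")
  P <- atlas_prob_matrix(atlas)
  mass <- colSums(P)
  scores <- as.numeric(crossprod(P, as.numeric(m)))
  zero <- mass <= 0
  scores[!zero] <- scores[!zero] / mass[!zero]
  if (any(zero)) {
    scores[zero] <- NA_real_
    warning("area(s) with zero probability mass scored NA: ",
            paste(atlas$labels$name[zero], collapse = ", "))
  }
  names(scores) <- atlas$labels$name
  scores
}

#' Regional saliency matrix for a cohort
#'
#' @param maps list of saliency maps in cohort order.
#' @param atlas a `voxsal_atlas`.
#' @return subjects x areas numeric matrix with subject ids as row names.
#' @export
regional_matrix <- function(maps, atlas) {
  out <- t(vapply(maps, regional_scores, numeric(nrow(atlas$labels)),
                  atlas = atlas))
  rownames(out) <- vapply(maps, function(m)
    if (inherits(m, "voxsal_saliency")) m$subject_id else NA_character_,
    character(1))
  out
}

ci_half_width <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  1.96 * sd(x, na.rm = TRUE) / sqrt(n)
}

retained_rows <- function(mat, subjects, correct_only = TRUE) {
  keep <- rep(TRUE, nrow(subjects))
  if (correct_only) {
    if (anyNA(subjects$predicted_class))
      stop("predictions unset; run the classifier first")
    keep <- subjects$predicted_class == subjects$true_class
  }
  keep
}

#' Per-class regional saliency profiles
#'
#' Mean and 95 percent half-width (1.96 sd/sqrt(n)) per area per class,
#' computed over correctly classified subjects only (the misclassification
#' exclusion rule), unless `correct_only = FALSE`.
#'
#' @param mat subjects x areas matrix from [regional_matrix()].
#' @param subjects matching subject data.frame.
#' @param correct_only drop misclassified subjects first.
#' @return data.frame with class, area, n, mean, half_width.
#' @export
class_profiles <- function(mat, subjects, correct_only = TRUE) {
  stopifnot(nrow(mat) == nrow(subjects))
  keep <- retained_rows(mat, subjects, correct_only)
  out <- list()
  for (cl in c("PD", "CT")) {
    rows <- keep & subjects$true_class == cl
    if (sum(rows) < 2) stop("fewer than 2 retained subjects in class ", cl)
    sub <- mat[rows, , drop = FALSE]
    out[[cl]] <- data.frame(class = cl, area = colnames(mat),
                            n = sum(rows),
                            mean = colMeans(sub),
                            half_width = apply(sub, 2, ci_half_width),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Lobe-aggregated saliency profiles
#'
#' Per subject, a lobe-hemisphere score is the unweighted mean over member
#' areas; the profile is the per-class mean and 95 percent half-width of
#' those scores.
#'
#' @param mat subjects x areas matrix (columns in atlas label order).
#' @param atlas the atlas providing lobe/hemisphere labels.
#' @param subjects matching subject data.frame.
#' @param correct_only drop misclassified subjects first.
#' @return data.frame with lobe, hemisphere, class, n, mean, half_width.
#' @export
lobe_aggregate <- function(mat, atlas, subjects, correct_only = TRUE) {
  lab <- atlas$labels
  if (any(is.na(lab$lobe) | lab$lobe == "" |
            is.na(lab$hemisphere) | lab$hemisphere == ""))
    stop("areas without lobe/hemisphere assignment: ",
         paste(lab$name[is.na(lab$lobe) | lab$lobe == "" |
                          is.na(lab$hemisphere) | lab$hemisphere == ""],
               collapse = ", "))
  keep <- retained_rows(mat, subjects, correct_only)
  groups <- split(seq_len(nrow(lab)), paste(lab$lobe, lab$hemisphere,
                                            sep = "|"))
  out <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    per_subject <- rowMeans(mat[, cols, drop = FALSE])
    lh <- strsplit(g, "|", fixed = TRUE)[[1]]
    for (cl in c("PD", "CT")) {
      rows <- keep & subjects$true_class == cl
      v <- per_subject[rows]
      out[[length(out) + 1L]] <-
        data.frame(lobe = lh[1], hemisphere = lh[2], class = cl,
                   n = sum(rows), mean = mean(v),
                   half_width = ci_half_width(v),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
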