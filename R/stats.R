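#' Exclude misclassified subjects from group analysis
#'
#' Subjects whose predicted class differs from their true class carry
#' saliency maps of the wrong class channel and would cross-contaminate the
#' class profiles, so they are removed before all group statistics.
#'
#' @param subjects data.frame with `true_class` and `predicted_class` set.
#' @return list with `retained` (subject data.frame), `keep` (logical
#'   vector), and `report` (excluded count per class).
#' @export
exclude_misclassified <- function(subjects) {
  if (anyNA(subjects$predicted_class))
    stop("predictions unset for some subjects")
  keep <- subjects$predicted_class == subjects$true_class
  report <- c(PD = sum(!keep & subjects$true_class == "PD"),
              CT = sum(!keep & subjects$true_class == "CT"))
  if (!any(keep))
    stop("every subject was misclassified; downstream analysis impossible")
  list(retained = subjects[keep, , drop = FALSE], keep = keep,
       report = report)
}

#' Mean regional saliency per fold
#'
#' Per-fold mean saliency vectors over that fold's held-out subjects, the
#' input to [interfold_regression()].
#' @param mat subjects x areas matrix.
#' @param subjects matching data.frame with `fold`.
#' @return folds x areas matrix.
#' @export
fold_mean_matrix <- function(mat, subjects) {
  folds <- sort(unique(subjects$fold))
  t(vapply(folds, function(f)
    colMeans(mat[subjects$fold == f, , drop = FALSE]),
    numeric(ncol(mat))))
}

#' Ordinary least squares alignment of mean saliency between folds
#'
#' For every unordered fold pair (i, j), regresses fold j's per-area mean
#' saliency on fold i's. Slopes near 1 and intercepts near 0 indicate the
#' folds learned similar regional representations.
#'
#' @param fold_means folds x areas matrix from [fold_mean_matrix()].
#' @return data.frame with fold_i, fold_j, b0 (intercept), b1 (slope).
#' @export
interfold_regression <- function(fold_means) {
  k <- nrow(fold_means)
  stopifnot(k >= 2)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- fold_means[i, ]; y <- fold_means[j, ]
      if (var(x) == 0) stop("zero-variance predictor in fold ", i)
      fit <- lm(y ~ x)
      out[[length(out) + 1L]] <-
        data.frame(fold_i = i, fold_j = j,
                   b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]))
    }
  }
  do.call(rbind, out)
}

#' Pairwise Kendall correlation across areas
#'
#' Tau-b for every pair of area columns with two-sided p-values (exact
#' enumeration for untied n <= 10, tie-corrected normal approximation
#' otherwise). Significance filtering is applied downstream
#' ([node_scores()]), not here.
#'
#' @param mat subjects x areas matrix (already restricted to the retained
#'   subjects).
#' @return A `voxsal_cortab`: `tau` and `pvals` (symmetric areas x areas
#'   matrices, unit/zero diagonal) and `n_subjects`.
#' @export
pairwise_kendall <- function(mat) {
  if (nrow(mat) < 3) stop("need at least 3 retained subjects")
  A <- ncol(mat)
  tau <- suppressWarnings(cor(mat, method = "kendall",
                              use = "pairwise.complete.obs"))
  pvals <- matrix(NA_real_, A, A, dimnames = dimnames(tau))
  diag(pvals) <- 0
  constant <- apply(mat, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (any(constant))
    warning("constant area column(s); tau undefined: ",
            paste(colnames(mat)[constant], collapse = ", "))
  for (i in seq_len(A - 1)) {
    for (j in (i + 1):A) {
      if (constant[i] || constant[j]) next
      kt <- kendall_test(mat[, i], mat[, j])
      pvals[i, j] <- pvals[j, i] <- kt$p
    }
  }
  diag(tau) <- ifelse(constant, NA_real_, 1)
  structure(list(tau = tau, pvals = pvals, n_subjects = nrow(mat)),
            class = "voxsal_cortab")
}

#' Validate a correlation table
#' @param ct a `voxsal_cortab`.
#' @return invisibly `TRUE`.
#' @export
validate_cortab <- function(ct) {
  stopifnot(inherits(ct, "voxsal_cortab"))
  ok <- !is.na(ct$tau)
  if (any(abs(ct$tau[ok]) > 1 + 1e-12)) stop("|tau| > 1")
  if (max(abs(ct$tau - t(ct$tau)), na.rm = TRUE) > 1e-12)
    stop("tau matrix not symmetric")
  d <- diag(ct$tau)
  if (any(abs(d[!is.na(d)] - 1) > 1e-12)) stop("diagonal tau != 1")
  p <- ct$pvals[!is.na(ct$pvals)]
  if (any(p < 0 | p > 1)) stop("p-values outside [0,1]")
  invisible(TRUE)
}

#' Node scores: signed sum of significant pairwise correlations
#'
#' `NS(a) = sum_{b != a} tau_{a,b} [p_{a,b} < alpha]`. A high node score
#' marks an area whose saliency co-varies with many others — a centrality
#' proxy over the saliency correlation network.
#'
#' @param ct a `voxsal_cortab`.
#' @param alpha significance threshold (raw p by default).
#' @param bh apply Benjamini-Hochberg adjustment to the off-diagonal
#'   p-values before thresholding (off by default; the reference procedure
#'   filters at raw p < 0.05).
#' @return named numeric vector of node scores.
#' @export
node_scores <- function(ct, alpha = 0.05, bh = FALSE) {
  validate_cortab(ct)
  p <- ct$pvals
  if (bh) {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = "BH")
    p[up] <- adj
    p <- pmin(p, t(p), na.rm = TRUE)
    dim(p) <- dim(ct$pvals)
  }
  sig <- !is.na(p) & p < alpha & !is.na(ct$tau)
  diag(sig) <- FALSE
  ns <- rowSums(ct$tau * sig, na.rm = TRUE)
  names(ns) <- rownames(ct$tau)
  ns
}

split_networks <- function(networks) {
  strsplit(as.character(networks), ";", fixed = TRUE)
}

#' Intra-network versus brain-wide saliency correlation
#'
#' For each area `a` in network `S`: `intra(a)` is the mean correlation with
#' the other members of `S`, `all(a)` the mean with all other areas. The
#' network summary is the mean of each, with 95 percent half-widths
#' (1.96 SEM) over member areas. By default signed tau over all pairs is
#' averaged; `abs_tau` averages magnitudes and `significant_only` restricts
#' to pairs with `p < alpha`.
#'
#' @param ct a `voxsal_cortab`.
#' @param networks per-area network membership (character vector, multiple
#'   memberships semicolon-separated), in the column order of `ct`.
#' @param abs_tau average `|tau|` instead of signed tau.
#' @param significant_only restrict to significant pairs.
#' @param alpha threshold used when `significant_only`.
#' @return data.frame with per-network intra/all means, half-widths, size.
#' @export
network_contrast <- function(ct, networks, abs_tau = FALSE,
                             significant_only = FALSE, alpha = 0.05) {
  validate_cortab(ct)
  A <- nrow(ct$tau)
  stopifnot(length(networks) == A)
  memb <- split_networks(networks)
  tau <- ct$tau
  if (abs_tau) tau <- abs(tau)
  if (significant_only) tau[!(ct$pvals < alpha)] <- NA
  diag(tau) <- NA
  nets <- sort(unique(unlist(memb)))
  out <- list()
  for (net in nets) {
    members <- which(vapply(memb, function(m) net %in% m, logical(1)))
    if (length(members) < 2)
      stop("network '", net, "' has fewer than 2 member areas")
    intra <- vapply(members, function(a)
      mean(tau[a, setdiff(members, a)], na.rm = TRUE), numeric(1))
    allv <- vapply(members, function(a)
      mean(tau[a, -a], na.rm = TRUE), numeric(1))
    out[[net]] <- data.frame(network = net, n_areas = length(members),
                             intra_mean = mean(intra),
                             intra_half_width = ci_half_width(intra),
                             all_mean = mean(allv),
                             all_half_width = ci_half_width(allv),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

metric_names <- function() c("updrs_p3", "moca", "ledd", "years_onset")

#' Association between regional saliency and a clinical metric
#'
#' Pearson and Kendall correlation of every area's saliency with one clinical
#' metric, over correctly classified PD subjects with the metric observed
#' (pairwise-complete). LEDD is restricted to medicated subjects. P-values
#' are unadjusted (flagged at p < 0.05) unless `bh = TRUE`.
#'
#' @param mat subjects x areas matrix (cohort order).
#' @param subjects matching subject data.frame with predictions set.
#' @param metric one of `"updrs_p3"`, `"moca"`, `"ledd"`, `"years_onset"`.
#' @param alpha significance threshold.
#' @param bh Benjamini-Hochberg adjust across areas before flagging.
#' @return data.frame with per-area correlations, p-values, n and
#'   significance flags.
#' @export
metric_association <- function(mat, subjects, metric = metric_names(),
                               alpha = 0.05, bh = FALSE) {
  metric <- match.arg(metric)
  stopifnot(nrow(mat) == nrow(subjects))
  keep <- retained_rows(mat, subjects) & subjects$true_class == "PD" &
    !is.na(subjects[[metric]])
  if (metric == "ledd") keep <- keep & subjects$medicated
  if (sum(keep) < 3)
    stop("fewer than 3 PD subjects with non-missing ", metric)
  y <- subjects[[metric]][keep]
  sub <- mat[keep, , drop = FALSE]
  res <- lapply(seq_len(ncol(sub)), function(a) {
    pe <- pearson_test(sub[, a], y)
    kt <- kendall_test(sub[, a], y)
    data.frame(area = colnames(sub)[a], metric = metric, n = pe$n,
               pearson_r = pe$r, pearson_p = pe$p,
               kendall_tau = kt$tau, kendall_p = kt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  pp <- out$pearson_p
  kp <- out$kendall_p
  if (bh) {
    pp <- stats::p.adjust(pp, method = "BH")
    kp <- stats::p.adjust(kp, method = "BH")
  }
  out$pearson_significant <- !is.na(pp) & pp < alpha
  out$kendall_significant <- !is.na(kp) & kp < alpha
  out
}

#' Pairwise correlation among clinical metrics
#'
#' Pearson and Kendall correlation for every pair of clinical metrics over
#' correctly classified PD subjects, overall and split by medication status.
#' Comparisons with fewer than 3 complete pairs are skipped with a note row.
#'
#' @param subjects subject data.frame with predictions set.
#' @return data.frame with group, metric pair, n, correlations and p-values.
#' @export
metric_pairwise <- function(subjects) {
  keep <- retained_rows(NULL, subjects) & subjects$true_class == "PD"
  pd <- subjects[keep, , drop = FALSE]
  groups <- list(all = rep(TRUE, nrow(pd)),
                 medicated = pd$medicated,
                 unmedicated = !pd$medicated)
  mets <- metric_names()
  out <- list()
  for (g in names(groups)) {
    sub <- pd[groups[[g]], , drop = FALSE]
    for (i in seq_len(length(mets) - 1)) {
      for (j in (i + 1):length(mets)) {
        x <- sub[[mets[i]]]; y <- sub[[mets[j]]]
        n_complete <- sum(!is.na(x) & !is.na(y))
        if (n_complete < 3) {
          out[[length(out) + 1L]] <-
            data.frame(group = g, metric_a = mets[i], metric_b = mets[j],
                       n = n_complete, pearson_r = NA_real_,
                       pearson_p = NA_real_, kendall_tau = NA_real_,
                       kendall_p = NA_real_, note = "insufficient pairs",
                       stringsAsFactors = FALSE)
          next
        }
        pe <- pearson_test(x, y)
        kt <- kendall_test(x, y)
        out[[length(out) + 1L]] <-
          data.frame(group = g, metric_a = mets[i], metric_b = mets[j],
                     n = n_complete, pearson_r = pe$r, pearson_p = pe$p,
                     kendall_tau = kt$tau, kendall_p = kt$p, note = "",
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
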