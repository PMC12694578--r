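# Kendall tau-b with two-sided p-values. Point estimates elsewhere use
# stats::cor(method = "kendall"); this file supplies the significance test:
# exact null by inversion-count (Mahonian) enumeration for untied samples
# with n <= 10, tie-corrected normal approximation otherwise.

# counts[d + 1] = number of permutations of 1..n with d inversions
mahonian_counts <- function(n) {
  counts <- 1
  if (n < 2) return(counts)
  for (m in 2:n) {
    width <- length(counts) + m - 1L
    new <- numeric(width)
    for (j in 0:(m - 1L)) {
      idx <- (j + 1L):(j + length(counts))
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  counts
}

#' Kendall rank correlation test (tau-b)
#'
#' Two-sided test of zero Kendall correlation. For untied data with n <= 10
#' the p-value is exact, from the full permutation null of the concordance
#' statistic; otherwise it uses the normal approximation with the standard
#' tie correction of the variance of S.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return list with `tau`, `p`, `n` (pairs used). `tau` is `NA` with a
#'   warning when either side is constant.
#' @export
kendall_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(tau = NA_real_, p = NA_real_, n = n))
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input; Kendall tau undefined")
    return(list(tau = NA_real_, p = NA_real_, n = n))
  }
  S <- sum(sign(outer(x, x, `-`)) * sign(outer(y, y, `-`))) / 2
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 10) {
    counts <- mahonian_counts(n)
    d <- 0:(length(counts) - 1L)   # inversion counts; S_null = n0 - 2d
    p <- sum(counts[abs(n0 - 2 * d) >= abs(S) - 1e-9]) / sum(counts)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- 2 * pnorm(-abs(z))
  }
  list(tau = tau, p = min(1, p), n = n)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Thin wrapper around [stats::cor.test()] returning `NA` (with a warning)
#' for constant input instead of erroring.
#' @param x,y numeric vectors; incomplete pairs dropped.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Pearson correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
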