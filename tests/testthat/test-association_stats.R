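test_that("misclassification exclusion applies the prediction rule", {
  s_all <- fake_subjects(c("PD", "PD", "CT"))
  ex <- exclude_misclassified(s_all)
  expect_equal(nrow(ex$retained), 3)
  expect_equal(unname(ex$report), c(0L, 0L))

  s_mix <- fake_subjects(c("PD", "PD", "CT"),
                         predicted = c("PD", "CT", "CT"))
  ex2 <- exclude_misclassified(s_mix)
  expect_equal(ex2$report[["PD"]], 1L)
  expect_equal(ex2$report[["CT"]], 0L)
  expect_equal(ex2$retained$id, c("S001", "S003"))

  s_wrong <- fake_subjects(c("PD", "CT"), predicted = c("CT", "PD"))
  expect_error(exclude_misclassified(s_wrong), "every subject")
  s_na <- fake_subjects("PD", predicted = NA_character_)
  expect_error(exclude_misclassified(s_na), "unset")
})

test_that("inter-fold regression recovers exact linear relations and OLS", {
  m <- matrix(runif(30), 2, 15)
  m[2, ] <- m[1, ]
  fit <- interfold_regression(m)
  expect_equal(fit$b1, 1)
  expect_equal(fit$b0, 0, tolerance = 1e-12)

  m[2, ] <- 2 * m[1, ] + 1
  fit2 <- interfold_regression(m)
  expect_equal(fit2$b1, 2)
  expect_equal(fit2$b0, 1)

  set.seed(4)
  m3 <- matrix(rnorm(4 * 25), 4, 25)
  fits <- interfold_regression(m3)
  expect_equal(nrow(fits), 6)
  for (r in seq_len(nrow(fits))) {
    x <- m3[fits$fold_i[r], ]; y <- m3[fits$fold_j[r], ]
    b1 <- cov(x, y) / var(x)          # closed-form OLS oracle
    b0 <- mean(y) - b1 * mean(x)
    expect_equal(fits$b1[r], b1, tolerance = 1e-10)
    expect_equal(fits$b0[r], b0, tolerance = 1e-10)
  }
  expect_error(interfold_regression(rbind(rep(1, 5), rnorm(5))),
               "zero-variance")
})

kendall_brute <- function(x, y) {
  # O(n^2) pair enumeration for tau-b
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

test_that("pairwise Kendall matches enumeration and handles degenerate input", {
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  expect_equal(kendall_test(x, y)$tau, -1 / 3)
  expect_equal(kendall_test(x, x)$tau, 1)

  set.seed(8)
  mat <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, paste0("a", 1:6)))
  ct <- pairwise_kendall(mat)
  expect_silent(validate_cortab(ct))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(ct$tau[i, j], kendall_brute(mat[, i], mat[, j]),
                 tolerance = 1e-12)

  mat_const <- cbind(mat, constant = 7)
  expect_warning(ctc <- pairwise_kendall(mat_const), "constant")
  expect_true(all(is.na(ctc$tau["constant", paste0("a", 1:6)])))
  expect_error(pairwise_kendall(mat[1:2, ]), "at least 3")
})

test_that("exact small-n Kendall p-values match the reference distribution", {
  set.seed(9)
  for (n in c(5, 8, 10)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- kendall_test(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall",
                                     exact = TRUE))
    expect_equal(mine$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # tie-corrected approximation agrees with cor.test's normal path
  x <- c(rnorm(20), 1, 1); y <- c(rnorm(20), 2, 2)
  mine <- kendall_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("node scores sum significant correlations per area", {
  tau <- matrix(c(1, 0.5, -0.2,
                  0.5, 1, 0.3,
                  -0.2, 0.3, 1), 3, 3)
  p <- matrix(c(0, 0.01, 0.2,
                0.01, 0, 0.04,
                0.2, 0.04, 0), 3, 3)
  ct <- manual_cortab(tau, p)
  expect_equal(unname(node_scores(ct)), c(0.5, 0.8, 0.3))

  # nothing significant
  ct0 <- manual_cortab(tau, matrix(0.5, 3, 3))
  expect_equal(unname(node_scores(ct0)), c(0, 0, 0))

  # saturated case: all pairs tau = 1 significant over A areas
  A <- 5
  ct1 <- manual_cortab(matrix(1, A, A), matrix(1e-6, A, A))
  expect_equal(unname(node_scores(ct1)), rep(A - 1, A))

  # permutation equivariance
  set.seed(10)
  mat <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, letters[1:4]))
  ctf <- pairwise_kendall(mat)
  ns <- node_scores(ctf)
  perm <- c(3, 1, 4, 2)
  ctp <- pairwise_kendall(mat[, perm])
  expect_equal(unname(node_scores(ctp)), unname(ns[perm]))
})

test_that("network contrast separates a planted two-block correlation structure", {
  # block latent factor generator: 100 subjects, two 5-area blocks
  set.seed(11)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  mat <- cbind(
    sapply(1:5, function(i) f1 + rnorm(n, 0, 0.8)),
    sapply(1:5, function(i) f2 + rnorm(n, 0, 0.8)))
  colnames(mat) <- paste0("a", 1:10)
  nets <- rep(c("blockA", "blockB"), each = 5)
  ct <- pairwise_kendall(mat)
  con <- network_contrast(ct, nets)
  for (r in 1:2) {
    expect_gt(con$intra_mean[r], con$all_mean[r])
    expect_gt(con$intra_mean[r] - con$intra_half_width[r],
              con$all_mean[r] + con$all_half_width[r])
  }
  # scrambling memberships destroys the contrast
  set.seed(12)
  con_perm <- network_contrast(ct, sample(nets))
  for (r in 1:2) {
    overlap <- abs(con_perm$intra_mean[r] - con_perm$all_mean[r]) <
      con_perm$intra_half_width[r] + con_perm$all_half_width[r]
    expect_true(overlap)
  }
  # perfectly concordant areas: intra = all = 1
  base <- rnorm(20)
  mat1 <- sapply(1:4, function(i) base)
  colnames(mat1) <- paste0("c", 1:4)
  con1 <- network_contrast(pairwise_kendall(mat1),
                           rep(c("n1", "n2"), each = 2))
  expect_equal(con1$intra_mean, c(1, 1))
  expect_equal(con1$all_mean, c(1, 1))
  expect_error(network_contrast(ct, c("solo", nets[-1])), "fewer than 2")
})

test_that("metric association flags planted relations and respects scoping", {
  subjects <- fake_subjects(rep("PD", 10))
  subjects$updrs_p3 <- 1:10
  subjects$medicated <- rep(c(TRUE, FALSE), 5)
  subjects$ledd <- ifelse(subjects$medicated, 100 + (1:10), NA)
  set.seed(13)
  mat <- matrix(rnorm(10 * 3), 10, 3,
                dimnames = list(subjects$id, paste0("a", 1:3)))
  mat[, 2] <- subjects$updrs_p3          # exact match
  assoc <- metric_association(mat, subjects, "updrs_p3")
  expect_equal(assoc$pearson_r[2], 1)
  expect_equal(assoc$kendall_tau[2], 1)
  expect_true(assoc$pearson_significant[2])
  # perfect linearity
  expect_equal(pearson_test(c(0, 1, 2), c(0, 2, 4))$r, 1)
  # LEDD restricted to medicated subjects
  assoc_ledd <- metric_association(mat, subjects, "ledd")
  expect_equal(unique(assoc_ledd$n), 5)
  # misclassified subjects are dropped
  subjects2 <- subjects
  subjects2$predicted_class[1:8] <- "CT"
  expect_error(metric_association(mat, subjects2, "updrs_p3"),
               "fewer than 3")
})

test_that("pairwise metric correlations recover the planted couplings", {
  atlas <- make_atlas(4, c(12, 12, 12), seed = 15)
  spec <- cohort_spec(n_per_class = 80, grid_shape = c(12L, 12L, 12L),
                      effect_areas = 1:2, clin_missing_frac = 0, seed = 15)
  coh <- make_cohort(spec, atlas)
  subjects <- coh$subjects
  subjects$predicted_class <- subjects$true_class
  mp <- metric_pairwise(subjects)
  row <- mp[mp$group == "all" & mp$metric_a == "moca" &
              mp$metric_b == "years_onset", ]
  expect_lt(row$pearson_r, 0)   # moca falls, years rise with severity
  expect_lt(row$pearson_p, 0.05)
  expect_true(all(c("all", "medicated", "unmedicated") %in% mp$group))
  # self-correlation of a metric is exactly 1
  expect_equal(pearson_test(subjects$updrs_p3, subjects$updrs_p3)$r, 1)
  expect_equal(kendall_test(subjects$updrs_p3, subjects$updrs_p3)$tau, 1)
})

test_that("independent metrics trigger at the nominal type-I rate", {
  set.seed(16)
  hits <- 0
  for (rep in 1:1000) {
    x <- rnorm(30); y <- rnorm(30)
    if (pearson_test(x, y)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.035)
  expect_lte(hits / 1000, 0.065)
})
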