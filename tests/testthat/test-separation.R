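test_that("Davies-Bouldin score matches hand evaluations", {
  # two singleton clusters at distinct points
  expect_equal(davies_bouldin(rbind(c(0, 0), c(5, 5)),
                              c("early", "late")), 0)
  # the 2x2 toy: S = 1 each, M = 10
  x <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  lab <- c("early", "early", "late", "late")
  expect_equal(davies_bouldin(x, lab), 0.2)
  # moving the clusters closer strictly increases the score
  x_close <- rbind(c(0, 0), c(0, 2), c(5, 0), c(5, 2))
  expect_gt(davies_bouldin(x_close, lab), davies_bouldin(x, lab))
  # coincident centroids are non-separable
  x_same <- rbind(c(0, 0), c(2, 2), c(0, 0), c(2, 2))
  expect_equal(davies_bouldin(x_same, lab), Inf)
})

test_that("the score is invariant to isometries and group relabeling", {
  x <- withr::with_seed(3, matrix(rnorm(40), ncol = 2))
  lab <- rep(c("early", "late"), each = 10)
  base <- davies_bouldin(x, lab)
  # translation
  expect_equal(davies_bouldin(x + 7, lab), base)
  # rotation
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(davies_bouldin(x %*% rot, lab), base)
  # which group is called early does not matter
  flip <- ifelse(lab == "early", "late", "early")
  expect_equal(davies_bouldin(x, flip), base)
})

test_that("permutation p-values are add-one corrected and deterministic", {
  x <- rbind(matrix(rnorm(30, 0), ncol = 3),
             matrix(rnorm(30, 50), ncol = 3))
  lab <- rep(c("early", "late"), each = 10)
  st1 <- dbs_permutation_test(x, lab, n_perm = 200, seed = 42)
  st2 <- dbs_permutation_test(x, lab, n_perm = 200, seed = 42)
  expect_identical(st1$null_scores, st2$null_scores)
  expect_identical(st1$p_value, st2$p_value)
  # centroid distance >> spread: observed beats every permutation
  expect_equal(st1$p_value, 1 / 201)
  expect_length(st1$null_scores, 200)
  expect_error(dbs_permutation_test(x, lab, n_perm = 50), "at least 100")
})

test_that("a tiny instance matches exhaustive label enumeration", {
  x <- withr::with_seed(11, matrix(rnorm(12, sd = 2), ncol = 2))
  lab <- rep(c("early", "late"), each = 3)
  obs <- davies_bouldin(x, lab)
  splits <- utils::combn(6, 3)
  exact <- mean(apply(splits, 2, function(idx) {
    ii <- logical(6); ii[idx] <- TRUE
    codontempo:::dbs_from_split(x, ii) <= obs
  }))
  st <- dbs_permutation_test(x, lab, n_perm = 4000, seed = 3)
  expect_equal(st$p_value, exact, tolerance = 0.04)
})

test_that("PCA projection is centered, unscaled, and matches an eigen oracle", {
  x <- withr::with_seed(21, matrix(rnorm(10 * 61), nrow = 10))
  pr <- pca_project(x)
  ev <- eigen(stats::cov(x))$values
  expect_equal(pr$var_explained, ev[1:2] / sum(ev), tolerance = 1e-9)

  # points already in a plane: two components explain everything
  basis <- withr::with_seed(22, qr.Q(qr(matrix(rnorm(61 * 2), ncol = 2))))
  planar <- withr::with_seed(23, matrix(rnorm(16), ncol = 2)) %*% t(basis)
  expect_equal(sum(pca_project(planar)$var_explained), 1, tolerance = 1e-9)

  # rotating the inputs leaves the projected geometry intact
  th <- 1.1
  rot <- diag(61); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                             -sin(th), cos(th)), 2)
  d1 <- dist(pca_project(x)$scores[, c("pc1", "pc2")])
  d2 <- dist(pca_project(x %*% rot)$scores[, c("pc1", "pc2")])
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-6)

  expect_error(pca_project(x[1:2, ]), "at least 3")
})

test_that("the maximum-margin line solves the plane toys", {
  ml <- max_margin_line(rbind(c(0, 0), c(2, 0)), c("early", "late"))
  expect_equal(abs(ml$a), 1)
  expect_equal(ml$b, 0)
  expect_equal(abs(ml$c), 1)  # the line x = 1
  expect_equal(ml$margin, 1)
  expect_true(ml$separable)

  # XOR configuration is not linearly separable
  xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  ml <- suppressWarnings(
    max_margin_line(xor, c("early", "early", "late", "late"), cost = 100)
  )
  expect_false(ml$separable)
})

test_that("the margin matches a brute-force orientation search", {
  brute_margin <- function(x, lab) {
    y <- ifelse(lab == "early", 1, -1)
    best <- 0
    for (th in seq(0, pi, length.out = 2001)) {
      w <- c(cos(th), sin(th))
      proj <- x %*% w
      lo <- max(proj[y == 1]); hi <- min(proj[y == -1])
      if (lo > hi) { tmp <- -proj; proj <- tmp
        lo <- max(proj[y == 1]); hi <- min(proj[y == -1]) }
      gap <- (hi - lo) / 2
      if (gap > best) best <- gap
    }
    best
  }
  for (seed in 1:3) {
    x <- withr::with_seed(seed, rbind(matrix(rnorm(12, 0, 0.5), ncol = 2),
                                      matrix(rnorm(12, 4, 0.5), ncol = 2)))
    lab <- rep(c("early", "late"), each = 6)
    ml <- max_margin_line(x, lab)
    expect_true(ml$separable)
    expect_equal(ml$margin, brute_margin(x, lab), tolerance = 0.02)
  }
})

test_that("the labeled-gene pipeline is reproducible end to end", {
  v <- synth_virus(synth_config(n_early = 10, n_late = 12,
                                divergence = 0.5, seed = 19))
  s1 <- separation_test(v$genes, n_perm = 200, seed = 7)
  s2 <- separation_test(v$genes, n_perm = 200, seed = 7)
  expect_identical(s1$dbs_observed, s2$dbs_observed)
  expect_identical(s1$null_scores, s2$null_scores)
  expect_identical(s1$p_value, s2$p_value)
  gl <- glance(s1)
  expect_equal(gl$n_early, 10)
  expect_equal(gl$n_late, 12)
  td <- tidy(s1)
  expect_equal(nrow(td), 200)
})

test_that("subsampling robustness validates its inputs and reports a fraction", {
  v <- synth_virus(synth_config(n_early = 12, n_late = 18,
                                divergence = 0.9, seed = 31))
  expect_error(
    subsample_robustness(v$genes, n_early = 20, n_late = 14,
                         n_rounds = 5, n_perm = 100),
    "found 12 early"
  )
  out <- subsample_robustness(v$genes, n_early = 8, n_late = 14,
                              n_rounds = 10, n_perm = 100, seed = 5)
  expect_equal(nrow(out$rounds), 10)
  expect_gte(out$fraction_significant, 0)
  expect_lte(out$fraction_significant, 1)
  out2 <- subsample_robustness(v$genes, n_early = 8, n_late = 14,
                               n_rounds = 10, n_perm = 100, seed = 5)
  expect_identical(out$rounds, out2$rounds)
})

test_that("rank-sum feature comparisons give exact small-sample p-values", {
  same <- wilcoxon_feature_separation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, 0)

  res <- wilcoxon_feature_separation(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_value, 0.1)  # exact two-sided 3-vs-3, full ordering
  expect_equal(res$direction, -1)

  swapped <- wilcoxon_feature_separation(c(10, 11, 12), c(1, 2, 3))
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$direction, 1)

  expect_error(wilcoxon_feature_separation(1, c(1, 2)), "at least 2")
})
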