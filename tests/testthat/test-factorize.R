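test_that("standardization centers, scales and flags zero-variance columns", {
  Z <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  out <- standardize_columns(Z, center = TRUE, scale = FALSE)
  expect_equal(out[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(attr(out, "zero_variance"), "b")
  out2 <- standardize_columns(Z)
  expect_equal(colnames(out2), "a")        # constant column dropped
  expect_equal(sd(out2[, 1]), 1)
  set.seed(4)
  R <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("x", "y", "z")))
  S <- standardize_columns(R)
  expect_equal(unname(colMeans(S)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(S, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("PCA scores match an SVD oracle and the stated sign convention", {
  set.seed(7)
  Z <- standardize_columns(matrix(rnorm(32), 8, 4,
                                  dimnames = list(NULL, paste0("m", 1:4))))
  p <- pca_scores(Z, 4)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-10)
  expect_equal(unname(apply(p$scores, 2, var)), p$eigenvalues,
               tolerance = 1e-10)
  # independent oracle: raw SVD, compared up to column sign
  sv <- svd(Z)
  oracle <- sv$u %*% diag(sv$d)
  for (j in 1:4) {
    agree <- min(sum(abs(p$scores[, j] - oracle[, j])),
                 sum(abs(p$scores[, j] + oracle[, j])))
    expect_lt(agree, 1e-8)
  }
  # sign convention: largest-|.| loading entry positive
  for (j in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # scores are mutually orthogonal and mean-zero
  expect_equal(unname(colMeans(p$scores)), rep(0, 4), tolerance = 1e-10)
  G <- crossprod(p$scores)
  expect_equal(G[lower.tri(G)], rep(0, 6), tolerance = 1e-8)
})

test_that("degenerate PCA inputs behave as documented", {
  z <- as.numeric(scale(c(1, 4, 2, 5, 3)))
  # duplicated column: eigenvalues (2, 0), PC1 = sqrt(2) * z, rank warning
  Z <- cbind(a = z, b = z)
  expect_warning(p <- pca_scores(Z, 2), "rank")
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(unname(p$scores[, 1]), sqrt(2) * z, tolerance = 1e-12)
  # single column: scores equal the column, unit eigenvalue
  p1 <- pca_scores(cbind(a = z), 1)
  expect_equal(unname(p1$scores[, 1]), z, tolerance = 1e-12)
  expect_equal(p1$eigenvalues, 1, tolerance = 1e-12)
})

test_that("pathway PCA keeps m* = min(F, usable metabolites) and skips degenerate pathways", {
  qt <- toy_qt(seed = 2, m = 10L)
  sb <- pathway_scores_pca(qt, colnames(qt$values)[1:7], 2)
  expect_equal(ncol(sb$scores), 2L)
  expect_equal(nrow(sb$scores), nrow(qt$values))
  sb2 <- pathway_scores_pca(qt, colnames(qt$values)[1:2], 2)
  expect_equal(ncol(sb2$scores), 2L)
  # constant member leaves a single usable metabolite -> skip signal
  qt$values[, "met_02"] <- 3
  expect_error(pathway_scores_pca(qt, c("met_01", "met_02"), 2),
               class = "pathlmm_pathway_skip")
  expect_error(pathway_scores_pca(qt, c("met_01", "unknown"), 2),
               class = "pathlmm_pathway_skip")
})

test_that("PCA scores are invariant to metabolite column order", {
  qt <- toy_qt(seed = 5, m = 8L)
  mem <- colnames(qt$values)[1:5]
  a <- pathway_scores_pca(qt, mem, 2)
  b <- pathway_scores_pca(qt, rev(mem), 2)
  expect_equal(a$scores, b$scores, tolerance = 1e-10)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-10)
})

test_that("partial-PCA scores match a per-block SVD oracle with first-eigenvalue weighting", {
  qt <- toy_qt(seed = 9, n_ind = 8L, m = 6L, times = c("t1", "t2"))
  mem <- colnames(qt$values)[1:4]
  sb <- pathway_scores_mfa(qt, mem, 2)
  expect_equal(dim(sb$scores), c(16L, 2L))
  expect_equal(names(sb$block_weights), c("t1", "t2"))
  # oracle: per-block standardize + SVD + 1/sqrt(lambda1) weight, sign-free
  glob <- pathway_scores_pca(qt, mem, 2)
  for (b in c("t1", "t2")) {
    rows <- qt$design$time == b
    Zb <- scale(qt$values[rows, mem])
    sv <- svd(Zb)
    l1 <- sv$d[1]^2 / (sum(rows) - 1)
    expect_equal(unname(sb$block_weights[b]), 1 / sqrt(l1), tolerance = 1e-10)
    for (j in 1:2) {
      o <- sv$u[, j] * sv$d[j] / sqrt(l1)
      agree <- min(sum(abs(sb$scores[rows, j] - o)),
                   sum(abs(sb$scores[rows, j] + o)))
      expect_lt(agree, 1e-8)
    }
  }
})

test_that("identical blocks give equal weights and aligned copies of one block", {
  # block t2 = block t1 with identical values per individual
  d <- toy_design(n_ind = 6L, times = c("t1", "t2"))
  set.seed(12)
  block <- matrix(exp(rnorm(6 * 4)), 6, 4)
  v <- rbind(block, block)
  dimnames(v) <- list(d$sample_id, paste0("m", 1:4))
  qt <- quant_table(v, d)
  sb <- pathway_scores_mfa(qt, paste0("m", 1:4), 2)
  expect_equal(unname(sb$block_weights["t1"]), unname(sb$block_weights["t2"]),
               tolerance = 1e-10)
  expect_equal(sb$scores[qt$design$time == "t1", ],
               sb$scores[qt$design$time == "t2", ],
               tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate single-block case reduces to weighted global PCA
  d1 <- toy_design(n_ind = 6L, times = "t1")
  qt1 <- quant_table(v[1:6, ], d1)
  sb1 <- pathway_scores_mfa(qt1, paste0("m", 1:4), 2)
  g1 <- pathway_scores_pca(qt1, paste0("m", 1:4), 2)
  expect_equal(sb1$scores, g1$scores / sqrt(g1$eigenvalues[1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("MFA blocks smaller than 3 observations are rejected", {
  d <- toy_design(n_ind = 2L, times = c("t1", "t2"))
  v <- matrix(runif(8), 4, 2, dimnames = list(d$sample_id, c("m1", "m2")))
  qt <- quant_table(v, d)
  expect_error(pathway_scores_mfa(qt, c("m1", "m2"), 2), "block too small")
})

test_that("time-blocked partial PCA erases a pure mean-shift time effect", {
  qt <- toy_qt(seed = 21, n_ind = 8L, m = 6L)
  mem <- colnames(qt$values)[1:5]
  shifted <- inject_time_effect(qt, mem,
                                gamma_t = c(t1 = 1, t2 = 5, t3 = 10),
                                noise_factor = 0.01, seed = 1)
  sb <- pathway_scores_mfa(shifted, mem, 2)
  r2 <- summary(lm(sb$scores[, 1] ~ shifted$design$time))$r.squared
  expect_lt(r2, 0.05)
  # while global PCA keeps the shift clearly visible
  sg <- pathway_scores_pca(shifted, mem, 2)
  r2g <- summary(lm(sg$scores[, 1] ~ shifted$design$time))$r.squared
  expect_gt(r2g, 0.5)
})
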