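test_that("correlation matrix basics and the affine CHI link", {
  t2 <- load_chromatographic_table()
  cm <- correlation_matrix(t2)
  expect_equal(diag(cm), rep(1, 9), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  # logk_IAM is (up to printing precision) an affine image of CHI_IAM
  expect_equal(cm["CHI_IAM", "logk_IAM"], 1, tolerance = 1e-3)
  # the five chromatographic lipophilicity indices correlate positively
  chrom5 <- c("logk_IAM", "CHI_logD", "logkw_C8", "logkw_CN", "logkw_Ph")
  expect_true(all(cm[chrom5, chrom5] > 0))
  expect_error(correlation_matrix(cbind(a = 1:5, b = rep(2, 5))), "b")
})

test_that("fixture extremes: compound 1 least, compound 4 most lipophilic", {
  t2 <- load_chromatographic_table()
  chrom5 <- c("logk_IAM", "CHI_logD", "logkw_C8", "logkw_CN", "logkw_Ph")
  for (m in chrom5)
    expect_equal(rownames(t2)[which.min(t2[, m])], "1")
  for (m in c("CHI_IAM", "CHI_logD", "logkw_C8", "logkw_Ph"))
    expect_equal(rownames(t2)[which.max(t2[, m])], "4")
})

test_that("PCA recovers known structure and is complete", {
  # two perfectly correlated columns: PC1 explains everything
  x <- rnorm(10)
  m <- cbind(a = x, b = 2 * x + 1)
  rownames(m) <- as.character(1:10)
  p1 <- lipo_pca(m, 1)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-12)
  # orthogonal equal-variance two-column case: ratios (0.5, 0.5)
  m2 <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  rownames(m2) <- as.character(1:4)
  p2 <- lipo_pca(m2, 2)
  expect_equal(p2$explained_variance_ratio, c(0.5, 0.5), tolerance = 1e-12)
  # completeness: full-rank reconstruction reproduces the standardized input
  m3 <- random_table(4, 3, seed = 5)
  p3 <- lipo_pca(m3, 3)
  z <- standardize_columns(m3)
  expect_equal(p3$scores %*% t(p3$loadings), unclass(z)[, ],
               ignore_attr = TRUE, tolerance = 1e-9)
  # explained ratios sum to 1 over all components, non-increasing
  expect_equal(sum(p3$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p3$explained_variance_ratio) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p3$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-9)
  # deterministic sign convention: largest-|loading| entry positive
  for (k in 1:3)
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, k])), k], 0)
  expect_error(lipo_pca(m3, 4), "n_components")
})

test_that("PCA agrees with prcomp up to the sign convention", {
  m <- random_table(12, 5, seed = 9)
  p <- lipo_pca(m, 5)
  ref <- prcomp(m, center = TRUE, scale. = TRUE)
  for (k in 1:5) {
    a <- p$loadings[, k]; b <- ref$rotation[, k]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-9)
  }
  expect_equal(p$explained_variance_ratio,
               unname(ref$sdev^2 / sum(ref$sdev^2)), tolerance = 1e-9)
})

test_that("Ward clustering matches a Lance-Williams recomputation", {
  set.seed(21)
  m <- matrix(rnorm(5 * 7), 7, 5,
              dimnames = list(as.character(1:7), paste0("M", 1:5)))
  d <- hierarchical_cluster(m, axis = "measures")
  z <- standardize_columns(m)
  oracle <- ward_oracle(t(unclass(z)), k = 2)
  expect_equal(sort(d$height), oracle$heights, tolerance = 1e-9)
  # partitions agree up to label permutation
  got <- cluster_membership(d, 2)
  agree <- table(got, oracle$membership[match(names(got), colnames(m))])
  expect_equal(sum(agree > 0), 2L)
})

test_that("degenerate clustering cases behave", {
  m <- cbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(5, 6, 9))
  rownames(m) <- as.character(1:3)
  d <- hierarchical_cluster(m, axis = "measures")
  # identical measures merge first at height 0
  expect_equal(min(d$height), 0)
  memb <- cluster_membership(d, 2)
  expect_equal(memb[["a"]], memb[["b"]])
  expect_false(memb[["a"]] == memb[["c"]])
  expect_equal(length(unique(cluster_membership(d, 3))), 3L)
  expect_equal(length(unique(cluster_membership(d, 1))), 1L)
  expect_error(cluster_membership(d, 4), "k must")
  # Ward heights non-decreasing
  expect_true(all(diff(d$height) >= -1e-12))
})

test_that("the packaged 13-measure table splits into computational vs experimental", {
  tab <- load_srd_table(include_pic50 = TRUE)
  d <- hierarchical_cluster(tab, axis = "measures")
  memb <- cluster_membership(d, 2)
  comp <- c("iLogP", "XLogP3", "WLogP", "MLogP", "SilicosIT_LogP",
            "Consensus_LogP", "KOWWIN_LogP")
  expect_equal(length(unique(memb[comp])), 1L)
})
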