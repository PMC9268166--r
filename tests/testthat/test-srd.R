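test_that("average ranks follow the tie convention", {
  expect_equal(rank_with_ties(c(0.1, 0.5, 0.9)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 1)), c(2.5, 2.5, 1))
  expect_equal(rank_with_ties(c(3, 1, 2, 2)), c(4, 1, 2.5, 2.5))
  expect_error(rank_with_ties(1), "at least 2")
  # rank sum invariant over random vectors
  for (s in 1:10) {
    set.seed(s)
    v <- sample(rnorm(8), 12, replace = TRUE)
    r <- rank_with_ties(v)
    expect_equal(sum(r), 12 * 13 / 2)
    expect_true(all(r >= 1 & r <= 12))
  }
})

test_that("the reference ranking is the row-mean ranking", {
  m <- random_table(4, 3, seed = 7)
  expect_equal(reference_ranking(m), rank(rowMeans(m)), ignore_attr = TRUE)
  # two identical columns: reference equals each column's ranking
  x <- c(0.3, -1, 2, 0.7)
  m2 <- cbind(a = x, b = x)
  expect_equal(reference_ranking(m2), rank(x), ignore_attr = TRUE)
  # rows sorted by mean -> identity ranking
  m3 <- m[order(rowMeans(m)), ]
  expect_equal(unname(reference_ranking(m3)), 1:4)
})

test_that("raw SRD and its normalization honour the extremes", {
  expect_equal(srd_value(1:5, 1:5), 0)
  expect_equal(srd_value(c(4, 3, 2, 1), 1:4), 8)
  expect_equal(srd_value(c(3, 2, 1), 1:3), 4)
  expect_error(srd_value(1:3, 1:4), "length")
  expect_equal(srd_max(4), 8)
  expect_equal(srd_max(3), 4)
  expect_equal(srd_max(27), 364)
  expect_equal(srd_normalize(0, 11), 0)
  expect_equal(srd_normalize(8, 4), 100)
  expect_error(srd_normalize(9, 4), "outside")
})

test_that("SRD parity is even for tie-free permutations", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:12, 1)
    expect_equal(srd_value(sample(n), sample(n)) %% 2, 0)
  }
})

test_that("exact CRRN matches literal enumeration and the analytic mean", {
  e3 <- crrn(3, method = "exact")
  expect_equal(e3$support, c(0, 2, 4))
  expect_equal(e3$prob, c(1, 2, 3) / 6)
  expect_equal(e3$mean, 8 / 3)
  e2 <- crrn(2, method = "exact")
  expect_equal(e2$support, c(0, 2))
  expect_equal(e2$prob, c(0.5, 0.5))
  for (n in 4:6) {
    ref <- crrn_enumerate(n)
    en <- crrn(n, method = "exact")
    expect_equal(en$support, as.numeric(names(ref)))
    expect_equal(en$prob, unname(c(ref)))
    expect_equal(en$mean, (n^2 - 1) / 3, tolerance = 1e-12)
  }
  expect_error(crrn(11, method = "exact"), "monte_carlo")
})

test_that("Monte-Carlo CRRN agrees with exact enumeration for small n", {
  for (n in c(5, 8)) {
    ex <- crrn(n, method = "exact")
    mc <- crrn(n, method = "monte_carlo", n_draws = 5e4, seed = 3)
    # quantiles agree within the lattice spacing of the (even) support
    expect_true(all(abs(mc$quantiles - ex$quantiles) <= 2))
    se <- sd(mc$draws) / sqrt(mc$n_draws)
    expect_lt(abs(mc$mean - (n^2 - 1) / 3), 3 * se)
  }
})

test_that("the Wilcoxon matched-pair test matches brute-force enumeration", {
  # all-positive differences, n = 6: two-sided p = 2/2^6
  w <- wilcoxon_matched_pairs(11:16, 1:6)
  expect_equal(w$p_value, 0.03125)
  # ties in |d| handled exactly: compare against literal 2^n enumeration
  for (s in 1:8) {
    set.seed(s)
    x <- sample(seq(0.5, 4, by = 0.5), 8, replace = TRUE)
    y <- sample(seq(0.5, 4, by = 0.5), 8, replace = TRUE)
    if (all(x == y)) next
    w <- wilcoxon_matched_pairs(x, y)
    expect_equal(w$p_value, wilcoxon_enumerate(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with the standard exact test
  set.seed(42)
  x <- rnorm(10); y <- rnorm(10)
  w <- wilcoxon_matched_pairs(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  # degenerate all-zero differences
  z <- wilcoxon_matched_pairs(1:5, 1:5)
  expect_true(z$all_zero)
  expect_equal(z$p_value, 1)
})

test_that("a measure equal to the row means gets SRD 0, whole analysis coherent", {
  set.seed(10)
  base <- matrix(rnorm(27 * 3), 27, 3,
                 dimnames = list(as.character(1:27), c("a", "b", "c")))
  zb <- scale_for_srd(base, "range")
  m <- cbind(ref_copy = rowMeans(zb), zb)
  s <- srd(m, scaling = "none", n_draws = 2e3, cv_folds = 0, seed = 1)
  expect_equal(unname(s$srd_raw["ref_copy"]), 0)
  expect_equal(s$ordering[1], "ref_copy")
  expect_true(all(s$srd_pct >= 0 & s$srd_pct <= 100))
  expect_setequal(s$ordering, colnames(m))
})

test_that("7-fold cross-validation returns k values per measure and honours contracts", {
  m <- random_table(27, 5, seed = 3)
  cv <- srd_crossvalidate(m, k = 7, seed = 2)
  expect_equal(dim(cv$cv_pct), c(7L, 5L))
  expect_equal(as.integer(sort(table(cv$fold))), c(3L, 4L, 4L, 4L, 4L, 4L, 4L))
  expect_error(srd_crossvalidate(m, k = 28), "\\[2, ")
  expect_error(srd_crossvalidate(m, k = 1), "\\[2, ")
  # same seed, same partition
  cv2 <- srd_crossvalidate(m, k = 7, seed = 2)
  expect_identical(cv$cv_pct, cv2$cv_pct)
})

test_that("srd on the packaged table ranks consensus logP closest to the reference", {
  tab <- load_srd_table()
  s <- srd(tab, n_draws = 5e4, seed = 11)
  expect_equal(s$ordering[1], "Consensus_LogP")
  expect_setequal(rev(s$ordering)[1:3],
                  c("logkw_CN", "CHI_logD", "logkw_Ph"))
  expect_equal(names(which.min(s$cv$median)), "Consensus_LogP")
  # Wilcoxon matrix is symmetric with unit diagonal
  expect_equal(diag(s$pairwise_wilcoxon), rep(1, 12), ignore_attr = TRUE)
  expect_equal(s$pairwise_wilcoxon, t(s$pairwise_wilcoxon))
})

test_that("the least-noisy synthetic measure attains the smallest SRD almost always", {
  hits <- 0L
  noise <- c(0.1, rep(1, 5))
  for (s in 1:100) {
    tl <- make_lipo_table(n_compounds = 27, n_measures = 6,
                          noise_sds = noise, slopes = rep(1, 6), seed = s)
    z <- scale_for_srd(tl$table, "range")
    ref <- reference_ranking(z)
    raw <- apply(apply(z, 2, rank_with_ties), 2, srd_value,
                 reference_ranks = ref)
    hits <- hits + (which.min(raw) == 1L)
  }
  expect_gte(hits, 95L)
})
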