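test_that("full-rank PLS equals ordinary least squares", {
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 0, 1.5)) + rnorm(12, sd = 0.2)
  f <- pls_fit(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(f$fitted.values, unname(fitted(ols)), tolerance = 1e-8)
  # prediction path agrees too
  Xn <- matrix(rnorm(15), 3, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_equal(predict(f, Xn),
               unname(cbind(1, Xn) %*% coef(ols))[, 1], tolerance = 1e-8)
})

test_that("1-LV single-descriptor PLS is simple linear regression", {
  set.seed(32)
  x <- rnorm(10)
  y <- 2 * x + rnorm(10, sd = 0.3)
  f <- pls_fit(cbind(d = x), y, 1)
  slr <- lm(y ~ x)
  expect_equal(f$fitted.values, unname(fitted(slr)), tolerance = 1e-10)
  expect_equal(unname(coef(f)["d"]), unname(coef(slr)[2]), tolerance = 1e-10)
})

test_that("PLS is invariant to row permutation and exact on noiseless data", {
  set.seed(33)
  X <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(0, 2, 0, 0, 0))
  f1 <- pls_fit(cbind(d = X[, 2]), y, 1)
  expect_lt(max(abs(residuals(f1))), 1e-10)
  f <- pls_fit(X, y, 3)
  prm <- sample(16)
  fp <- pls_fit(X[prm, ], y[prm], 3)
  expect_equal(coef(f), coef(fp), tolerance = 1e-10)
  # prediction at the training centroid is the training mean
  expect_equal(unname(predict(f, matrix(colMeans(X), 1,
                                        dimnames = list(NULL, colnames(X))))),
               mean(y), tolerance = 1e-10)
  # shifting X shifts predictions linearly
  shift <- rep(1, 5)
  expect_equal(predict(f, sweep(X, 2, shift, "+")),
               f$fitted.values + sum(coef(f) * shift), tolerance = 1e-8)
  expect_error(predict(f, X[, 1:3]), "missing descriptor")
})

test_that("pls_fit contracts: zero variance and rank limits", {
  X <- cbind(a = rnorm(8), b = rep(1, 8))
  expect_error(pls_fit(X, rnorm(8), 1), "zero-variance")
  X2 <- cbind(a = rnorm(8), b = rnorm(8))
  X2 <- cbind(X2, c = X2[, "a"] + X2[, "b"])
  expect_error(pls_fit(X2, rnorm(8), 3), "rank")
})

test_that("leave-one-out Q2 matches hand arithmetic and behaves on noise", {
  # hand-computable single-descriptor case
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  loo <- q2_loo(cbind(d = x), y, 1)
  pred <- sapply(1:4, function(i) {
    fit <- lm(y[-i] ~ x[-i])
    unname(coef(fit)[1] + coef(fit)[2] * x[i])
  })
  expect_equal(loo$predictions, pred, tolerance = 1e-10)
  expect_equal(loo$q2_loo, 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(loo$rmse_cv, sqrt(sum((y - pred)^2) / 4), tolerance = 1e-10)
  # noiseless linear data: perfect
  set.seed(34)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  yy <- drop(X %*% c(1, 2))
  loo2 <- q2_loo(X, yy, 2)
  expect_equal(loo2$q2_loo, 1, tolerance = 1e-8)
  expect_lt(loo2$rmse_cv, 1e-8)
  # pure-noise endpoints rarely cross-validate
  ok <- 0L
  for (s in 1:100) {
    set.seed(400 + s)
    Xn <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    yn <- rnorm(20)
    ok <- ok + (q2_loo(Xn, yn, 2)$q2_loo < 0.3)
  }
  expect_gte(ok, 95L)
})

test_that("validation statistics equal an independent formula transcription", {
  for (s in 1:100) {
    set.seed(500 + s)
    yo_tr <- rnorm(10); yp_tr <- yo_tr + rnorm(10, sd = 0.3)
    yo_e <- rnorm(10, mean = 0.4); yp_e <- yo_e + rnorm(10, sd = 0.5)
    got <- validation_stats(yo_tr, yp_tr, yo_e, yp_e)
    ref <- validation_oracle(yo_tr, yp_tr, yo_e, yp_e)
    for (nm in names(ref))
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-10)
    # Q2F1 >= Q2F2 when the external mean differs from the training mean
    expect_gte(got$q2_f1, got$q2_f2 - 1e-12)
  }
})

test_that("validation statistics hit their exact limits", {
  yo <- c(1, 2, 3, 4); yp <- yo
  v <- validation_stats(yo, yo, yo, yp)
  expect_equal(v$q2_f1, 1); expect_equal(v$q2_f2, 1)
  expect_equal(v$q2_f3, 1); expect_equal(v$ccc, 1)
  expect_equal(v$rmse_p, 0)
  # external predictions pinned at the external mean: Q2F2 = 0
  v2 <- validation_stats(c(0, 1, 2), c(0, 1, 2), c(1, 2, 3),
                         rep(2, 3))
  expect_equal(v2$q2_f2, 0)
  # degenerate denominator flagged, not infinite
  v3 <- validation_stats(c(1, 1, 1), c(1, 1, 1), c(1, 2), c(1, 2))
  expect_true("r2" %in% v3$undefined)
  expect_true(is.na(v3$r2))
})

test_that("CCC is 1 only for perfect agreement", {
  set.seed(35)
  yo <- rnorm(8)
  expect_equal(validation_stats(yo, yo, yo, yo)$ccc, 1)
  expect_lt(validation_stats(yo, yo, yo, yo + 0.5)$ccc, 1)
  expect_lt(validation_stats(yo, yo, yo, 2 * yo)$ccc, 1)
})
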