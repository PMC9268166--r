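#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a single-response PLS model by sequential NIPALS extraction of latent
#' variables on autoscaled descriptors and centered response, with deflation
#' of X after each component. Deterministic for fixed input. For single-y
#' PLS the NIPALS weight step closes after one pass (w is proportional to
#' X'y), so no inner iteration is needed.
#'
#' @param X descriptor matrix (n x p), no zero-variance columns.
#' @param y numeric response, length n.
#' @param n_components number of latent variables (>= 1, <= rank of the
#'   centered X).
#' @return object of class `pls` holding weights, loadings, regression
#'   coefficients on the original descriptor scale, and the
#'   centering/scaling constants.
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows of X must match length of y")
  if (n < n_components + 2L) stop("too few observations for ", n_components,
                                  " components")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  if (any(x_scale == 0))
    stop("zero-variance descriptor(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  y_center <- mean(y)
  Xs <- sweep(sweep(X, 2L, x_center, "-"), 2L, x_scale, "/")
  rk <- qr(Xs)$rank
  if (n_components < 1L || n_components > rk)
    stop("n_components must be in [1, rank(X) = ", rk, "]")
  core <- .pls1_nipals(Xs, y - y_center, n_components)
  structure(list(n_components = n_components,
                 x_weights = core$W, x_loadings = core$P,
                 y_loadings = core$q, scores = core$TT,
                 coef_scaled = core$b,
                 coefficients = core$b / x_scale,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center,
                 descriptor_names = colnames(X),
                 fitted.values = y_center + drop(Xs %*% core$b),
                 y = y,
                 training_ids = rownames(X)),
            class = "pls")
}

# NIPALS core on pre-scaled X, centered y
.pls1_nipals <- function(Xs, yc, A) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, A)
  TT <- matrix(0, n, A)
  q <- numeric(A)
  E <- Xs; f <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("residual X carries no covariance with y at LV ", a)
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; q[a] <- qa
  }
  # coefficients on the scaled X: b = W (P'W)^-1 q
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, TT = TT, q = q, b = b)
}

#' @export
print.pls <- function(x, ...) {
  cat(sprintf("PLS1 model: %d latent variable(s), %d descriptors, n = %d\n",
              x$n_components, length(x$coefficients), length(x$y)))
  cat("R2 (training):",
      format(1 - sum((x$y - x$fitted.values)^2) /
               sum((x$y - mean(x$y))^2), digits = 4), "\n")
  invisible(x)
}

#' @export
coef.pls <- function(object, scaled = FALSE, ...) {
  b <- if (scaled) object$coef_scaled else object$coefficients
  stats::setNames(b, object$descriptor_names)
}

#' @export
residuals.pls <- function(object, ...) object$y - object$fitted.values

#' @export
predict.pls <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    miss <- setdiff(object$descriptor_names, colnames(X))
    if (length(miss))
      stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
    X <- X[, object$descriptor_names, drop = FALSE]
  } else if (ncol(X) != length(object$descriptor_names)) {
    stop("newdata must have ", length(object$descriptor_names), " columns")
  }
  Xs <- sweep(sweep(X, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  object$y_center + drop(Xs %*% object$coef_scaled)
}

#' @export
summary.pls <- function(object, ...) {
  print(object)
  ssy <- cumsum(object$y_loadings^2 * colSums(object$scores^2))
  cat("cumulative y-variance captured per LV:",
      paste(sprintf("%.3f", ssy / sum((object$y - mean(object$y))^2)),
            collapse = " "), "\n")
  invisible(object)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Each observation is held out in turn, the model refit on the remaining
#' n - 1, and the held-out response predicted. `q2_loo = 1 - PRESS/TSS` with
#' TSS about the full-training mean; `rmse_cv = sqrt(PRESS/n)`.
#'
#' @inheritParams pls_fit
#' @return list with `q2_loo`, `rmse_cv`, and the LOO predictions.
#' @export
q2_loo <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 observations for LOO")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], n_components)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(q2_loo = 1 - press / tss, rmse_cv = sqrt(press / n),
       predictions = pred)
}

#' External-validation statistics for QSRR/QSAR models
#'
#' Implements the standard battery: training R2; external Q2F1 (residual sum
#' of squares against deviations of the external observations from the
#' *training* mean), Q2F2 (against the external mean), Q2F3 (per-observation
#' variance normalized by the training set), RMSEP, and Lin's concordance
#' correlation coefficient (CCC) on the external set.
#'
#' @param y_obs_tr,y_pred_tr observed/predicted responses, training set.
#' @param y_obs_ext,y_pred_ext observed/predicted responses, external set.
#' @return object of class `validation_stats`: r2, q2_f1, q2_f2, q2_f3,
#'   rmse_p, ccc, n_tr, n_ext; statistics with a zero denominator are `NA`
#'   and listed in the `undefined` field.
#' @export
validation_stats <- function(y_obs_tr, y_pred_tr, y_obs_ext, y_pred_ext) {
  if (length(y_obs_tr) != length(y_pred_tr) ||
      length(y_obs_ext) != length(y_pred_ext))
    stop("observed and predicted vectors differ in length")
  if (!length(y_obs_tr) || !length(y_obs_ext))
    stop("empty observation vectors")
  n_tr <- length(y_obs_tr); n_ext <- length(y_obs_ext)
  m_tr <- mean(y_obs_tr); m_ext <- mean(y_obs_ext)
  undefined <- character(0)
  safe_ratio <- function(num, den, name) {
    if (abs(den) < 1e-300) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  ss_res_tr <- sum((y_obs_tr - y_pred_tr)^2)
  ss_res_ext <- sum((y_obs_ext - y_pred_ext)^2)
  r2 <- 1 - safe_ratio(ss_res_tr, sum((y_obs_tr - m_tr)^2), "r2")
  q2_f1 <- 1 - safe_ratio(ss_res_ext, sum((y_obs_ext - m_tr)^2), "q2_f1")
  q2_f2 <- 1 - safe_ratio(ss_res_ext, sum((y_obs_ext - m_ext)^2), "q2_f2")
  q2_f3 <- 1 - safe_ratio(ss_res_ext / n_ext,
                          sum((y_obs_tr - m_tr)^2) / n_tr, "q2_f3")
  rmse_p <- sqrt(ss_res_ext / n_ext)
  mp_ext <- mean(y_pred_ext)
  ccc_den <- sum((y_obs_ext - m_ext)^2) + sum((y_pred_ext - mp_ext)^2) +
    n_ext * (m_ext - mp_ext)^2
  ccc <- safe_ratio(2 * sum((y_obs_ext - m_ext) * (y_pred_ext - mp_ext)),
                    ccc_den, "ccc")
  structure(list(r2 = r2, q2_f1 = q2_f1, q2_f2 = q2_f2, q2_f3 = q2_f3,
                 rmse_p = rmse_p, ccc = ccc,
                 n_tr = n_tr, n_ext = n_ext, undefined = undefined),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  v <- unlist(x[c("r2", "q2_f1", "q2_f2", "q2_f3", "rmse_p", "ccc")])
  cat("External-validation statistics (n_tr =", x$n_tr,
      ", n_ext =", x$n_ext, ")\n")
  print(round(v, 4))
  if (length(x$undefined))
    cat("undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
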