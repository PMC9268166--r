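#' Average ranks with ties
#'
#' Ascending ranks; tied values share the mean of the positions they occupy.
#'
#' @param values finite numeric vector, length >= 2.
#' @return rank vector; sums to n(n+1)/2.
#' @export
rank_with_ties <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to rank")
  .check_finite(values, "values")
  rank(values, ties.method = "average")
}

#' Row-average reference ranking
#'
#' The consensus reference of the SRD procedure: compounds ranked by the mean
#' of their (standardized) measure values.
#'
#' @param table numeric matrix, compounds in rows; should be standardized so
#'   the row mean is scale-free.
#' @return rank vector over compounds.
#' @export
reference_ranking <- function(table) {
  if (is.null(dim(table)) || nrow(table) < 2L || ncol(table) < 1L)
    stop("table must have at least 2 rows and 1 column")
  rank_with_ties(rowMeans(table))
}

#' Raw SRD value
#'
#' City-block distance between a measure's ranking and the reference ranking:
#' `sum_i |r_i - ref_i|`.
#'
#' @param column_ranks,reference_ranks equal-length rank vectors.
#' @return non-negative scalar.
#' @export
srd_value <- function(column_ranks, reference_ranks) {
  if (length(column_ranks) != length(reference_ranks))
    stop("rank vectors differ in length")
  sum(abs(column_ranks - reference_ranks))
}

#' Maximum attainable SRD
#'
#' For n objects the complete reversal gives `n^2/2` (n even) or
#' `(n^2 - 1)/2` (n odd).
#'
#' @param n_objects number of ranked objects.
#' @export
srd_max <- function(n_objects) {
  if (n_objects %% 2 == 0) n_objects^2 / 2 else (n_objects^2 - 1) / 2
}

#' Normalize SRD to percent of maximum
#'
#' @param srd_raw raw SRD value(s) in `[0, srd_max(n_objects)]`.
#' @param n_objects number of ranked objects.
#' @return SRD% in `[0, 100]`.
#' @export
srd_normalize <- function(srd_raw, n_objects) {
  mx <- srd_max(n_objects)
  if (any(srd_raw < 0 | srd_raw > mx))
    stop("srd_raw outside [0, ", mx, "]")
  100 * srd_raw / mx
}

# -- CRRN: the SRD null distribution under random rankings ------------------

# Exact distribution of sum_i |p(i) - i| over uniform random permutations,
# computed as the polynomial permanent of the matrix x^{|i-j|} via Ryser's
# formula. Equivalent to full enumeration of the n! permutations but feasible
# up to n = 10.
.crrn_exact_counts <- function(n) {
  maxd <- srd_max(n)
  # rows[[i]][d+1] accumulates x^{|i-j|} over j in the current subset
  total <- numeric(maxd + 1L)
  subset <- integer(0)
  rowsum_poly <- matrix(0, nrow = n, ncol = maxd + 1L)
  # iterate subsets in Gray-code order, updating row sums incrementally
  prev <- 0L
  for (g in seq_len(2^n - 1L)) {
    gray <- bitwXor(g, bitwShiftR(g, 1L))
    changed <- bitwXor(gray, prev)
    j <- as.integer(log2(changed)) + 1L  # element toggled
    sgn <- if (bitwAnd(gray, changed) != 0L) +1 else -1
    for (i in seq_len(n)) {
      d <- abs(i - j)
      rowsum_poly[i, d + 1L] <- rowsum_poly[i, d + 1L] + sgn
    }
    prev <- gray
    k <- sum(as.integer(intToBits(gray)))  # subset size
    # product of the n row polynomials
    prod_poly <- c(1, numeric(maxd))
    ok <- TRUE
    for (i in seq_len(n)) {
      ri <- rowsum_poly[i, ]
      if (!any(ri != 0)) { ok <- FALSE; break }
      cp <- numeric(maxd + 1L)
      nz <- which(ri != 0)
      for (d in nz) {
        lim <- maxd + 2L - d
        cp[d:(maxd + 1L)] <- cp[d:(maxd + 1L)] +
          ri[d] * prod_poly[seq_len(lim)]
      }
      prod_poly <- cp
    }
    if (ok) {
      sign_term <- (-1)^(n - k)
      total <- total + sign_term * prod_poly
    }
  }
  counts <- round(total)
  names(counts) <- 0:maxd
  counts[counts > 0.5]
}

#' SRD null distribution (comparison of ranks by random numbers)
#'
#' Distribution of the SRD statistic when a random (uniform) permutation of n
#' objects is compared with a fixed reference ranking. `"exact"` computes the
#' full enumeration distribution (n <= 10); `"monte_carlo"` samples random
#' permutations.
#'
#' @param n_objects number of ranked objects (>= 2).
#' @param method `"exact"` or `"monte_carlo"`; default exact for n <= 10.
#' @param n_draws Monte-Carlo sample size (default 1e6).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @return an object of class `crrn` with the support/probabilities (exact)
#'   or draws (MC), the 5/25/50/75/95% quantiles, and the mean.
#' @export
crrn <- function(n_objects, method = c("auto", "exact", "monte_carlo"),
                 n_draws = 1e6, seed = NULL) {
  if (n_objects < 2L) stop("n_objects must be >= 2")
  method <- match.arg(method)
  if (method == "auto") method <- if (n_objects <= 10L) "exact" else "monte_carlo"
  if (method == "exact" && n_objects > 10L)
    stop("exact enumeration supported for n_objects <= 10; use monte_carlo")
  if (method == "exact") {
    counts <- .crrn_exact_counts(n_objects)
    support <- as.numeric(names(counts))
    prob <- counts / sum(counts)
    cum <- cumsum(prob)
    qq <- vapply(c(.05, .25, .5, .75, .95),
                 function(p) support[which(cum >= p)[1L]], 0)
    out <- list(n_objects = n_objects, method = "exact",
                support = support, prob = unname(prob),
                quantiles = stats::setNames(qq, c("xx1", "q1", "median", "q3", "xx19")),
                mean = sum(support * prob))
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- seq_len(n_objects)
    draws <- vapply(seq_len(n_draws),
                    function(i) sum(abs(sample.int(n_objects) - idx)),
                    numeric(1))
    qq <- stats::quantile(draws, c(.05, .25, .5, .75, .95), names = FALSE)
    out <- list(n_objects = n_objects, method = "monte_carlo",
                draws = draws, n_draws = n_draws,
                quantiles = stats::setNames(qq, c("xx1", "q1", "median", "q3", "xx19")),
                mean = mean(draws))
  }
  class(out) <- "crrn"
  out
}

#' @export
print.crrn <- function(x, ...) {
  cat(sprintf("CRRN null distribution, n = %d (%s%s)\n", x$n_objects,
              x$method,
              if (x$method == "monte_carlo")
                sprintf(", %g draws", x$n_draws) else ""))
  cat("quantiles (5/25/50/75/95%):",
      paste(format(x$quantiles, digits = 4), collapse = "  "), "\n")
  cat("mean:", format(x$mean, digits = 6),
      sprintf("(analytic (n^2-1)/3 = %.4f)\n", (x$n_objects^2 - 1) / 3))
  invisible(x)
}

# -- Wilcoxon matched-pair signed-rank test ---------------------------------

# Exact null distribution of the signed-rank sum W+ by generating-function
# convolution over the 2^n sign assignments; ranks are doubled so average
# (tied) ranks become integers. Identical to literal enumeration.
.signed_rank_exact_p <- function(W, r) {
  r2 <- round(2 * r)
  poly <- c(1)                         # coefficients over W+ on the 2x scale
  for (ri in r2) {
    shifted <- c(numeric(ri), poly)
    length(poly) <- length(shifted)
    poly[is.na(poly)] <- 0
    poly <- poly + shifted
  }
  prob <- poly / sum(poly)
  support <- seq_along(prob) - 1L      # W+ values on the doubled scale
  w2 <- round(2 * W)
  mu <- sum(r2) / 2
  # two-sided: fold around the null mean
  dev <- abs(w2 - mu)
  min(1, sum(prob[abs(support - mu) >= dev - 1e-9]))
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Two-sided test for paired samples. Zero differences are dropped
#' (Wilcoxon's convention); p is exact (enumeration over sign assignments,
#' ties handled by average ranks) for up to 25 informative pairs, and uses
#' the normal approximation with tie correction beyond that.
#'
#' @param x,y equal-length paired samples.
#' @return list with `statistic` (W+, sum of positive ranks), `p_value`,
#'   `n_used` informative pairs, `method`, and `all_zero` flag.
#' @export
wilcoxon_matched_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples differ in length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate", all_zero = TRUE))
  n <- length(d)
  if (n < 3L)
    warning("fewer than 3 informative pairs; test has no power")
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= 25L) {
    p <- .signed_rank_exact_p(W, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_used = n, method = method,
       all_zero = FALSE)
}

# -- The full SRD analysis ---------------------------------------------------

#' Column scaling for the SRD consensus reference
#'
#' Per-column ranks are invariant to any monotone column transform, but the
#' row-average reference ranking is not: it depends on how the measures are
#' brought to a common scale. `"range"` (min-max, interval) scaling maps each
#' column to `[0, 1]`; `"zscore"` autoscales to mean 0 / SD 1; `"none"` uses
#' the raw values.
#'
#' @param table compounds x measures matrix.
#' @param scaling `"range"`, `"zscore"`, or `"none"`.
#' @return scaled matrix of the same shape.
#' @export
scale_for_srd <- function(table, scaling = c("range", "zscore", "none")) {
  scaling <- match.arg(scaling)
  switch(scaling,
         none = table,
         zscore = standardize_columns(table),
         range = {
           rng <- apply(table, 2L, range)
           span <- rng[2L, ] - rng[1L, ]
           if (any(span == 0))
             stop("zero-range column(s): ",
                  paste(colnames(table)[span == 0], collapse = ", "))
           sweep(sweep(table, 2L, rng[1L, ], "-"), 2L, span, "/")
         })
}

#' Sum of ranking differences analysis
#'
#' Standardizes the columns, builds the row-average reference ranking, and
#' computes each measure's raw SRD and SRD%; attaches the CRRN null
#' distribution for the number of compounds, a k-fold cross-validation of the
#' SRD% values, and the pairwise Wilcoxon matched-pair p-value matrix over the
#' CV values. Measures are reported in ascending SRD order (closest to the
#' consensus first).
#'
#' @param table `lipo_table` or numeric matrix, compounds x measures
#'   (>= 2 of each).
#' @param scaling column pre-scaling used to build the row-average reference
#'   (see [scale_for_srd()]); `"range"` by default. Per-measure ranks are
#'   unaffected by this choice.
#' @param crrn_method passed to [crrn()].
#' @param n_draws Monte-Carlo draws for the CRRN null.
#' @param cv_folds folds for [srd_crossvalidate()]; `0` skips CV.
#' @param seed integer seed controlling the CRRN draw and the CV partition.
#' @return object of class `srd`.
#' @export
srd <- function(table, scaling = "range", crrn_method = "auto",
                n_draws = 1e6, cv_folds = 7, seed = 1L) {
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least 2 compounds and 2 measures")
  z <- scale_for_srd(table, scaling)
  ref <- reference_ranking(z)
  n <- nrow(table)
  col_ranks <- apply(z, 2L, rank_with_ties)
  raw <- apply(col_ranks, 2L, srd_value, reference_ranks = ref)
  pct <- srd_normalize(raw, n)
  ord <- order(raw, colnames(table))
  null <- crrn(n, method = crrn_method, n_draws = n_draws, seed = seed)
  cv <- NULL
  wil <- NULL
  if (cv_folds >= 2) {
    cv <- srd_crossvalidate(table, k = cv_folds, scaling = scaling,
                            seed = seed)
    m <- ncol(table)
    wil <- matrix(NA_real_, m, m,
                  dimnames = list(colnames(table), colnames(table)))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      wil[i, j] <- if (i == j) 1 else
        wilcoxon_matched_pairs(cv$cv_pct[, i], cv$cv_pct[, j])$p_value
    }
  }
  structure(list(measure_names = colnames(table),
                 srd_raw = raw, srd_pct = pct,
                 reference_ranks = ref, crrn = null,
                 cv = cv, pairwise_wilcoxon = wil,
                 ordering = colnames(table)[ord],
                 scaling = scaling,
                 n_compounds = n, seed = seed),
            class = "srd")
}

#' @export
print.srd <- function(x, ...) {
  cat(sprintf("SRD analysis: %d measures, %d compounds (row-average reference)\n",
              length(x$measure_names), x$n_compounds))
  tab <- data.frame(SRD = x$srd_raw[x$ordering],
                    `SRD%` = round(x$srd_pct[x$ordering], 2),
                    check.names = FALSE)
  print(tab)
  q <- x$crrn$quantiles
  cat(sprintf("CRRN null (n = %d): 5%% = %g, median = %g, 95%% = %g\n",
              x$n_compounds, q[["xx1"]], q[["median"]], q[["xx19"]]))
  invisible(x)
}

#' @export
summary.srd <- function(object, ...) {
  cat(sprintf("Closest to consensus: %s (SRD = %g, SRD%% = %.2f)\n",
              object$ordering[1L], object$srd_raw[object$ordering[1L]],
              object$srd_pct[object$ordering[1L]]))
  below <- object$srd_raw < object$crrn$quantiles[["xx1"]]
  cat("Measures below the 5% random-ranking quantile:",
      paste(object$measure_names[below], collapse = ", "), "\n")
  if (!is.null(object$cv)) {
    med <- apply(object$cv$cv_pct, 2L, stats::median)
    cat(sprintf("Lowest %d-fold CV median SRD%%: %s (%.2f)\n",
                object$cv$k, names(which.min(med)), min(med)))
  }
  invisible(object)
}

#' @export
plot.srd <- function(x, ...) {
  ord <- x$ordering
  graphics::barplot(x$srd_pct[ord], names.arg = ord, las = 2,
                    ylab = "SRD%", main = "Sum of ranking differences", ...)
  q <- srd_normalize(x$crrn$quantiles, x$n_compounds)
  graphics::abline(h = q[c("xx1", "median", "xx19")], lty = c(2, 1, 2),
                   col = "grey40")
  invisible(x)
}

#' k-fold cross-validation of the SRD procedure
#'
#' Compounds are partitioned at random into k nearly equal folds; each fold
#' is left out in turn and the whole SRD computation (standardization,
#' row-average reference, SRD%) is repeated on the remaining compounds.
#'
#' @param table compounds x measures matrix.
#' @param k number of folds (2 <= k <= n).
#' @param scaling column pre-scaling, as in [srd()]; recomputed on each
#'   reduced compound set.
#' @param seed integer seed for the random partition.
#' @return list with `cv_pct` (k x measures matrix of SRD% values), fold
#'   assignment, and per-measure medians/quartiles.
#' @export
srd_crossvalidate <- function(table, k = 7, scaling = "range", seed = 1L) {
  n <- nrow(table)
  if (k < 2 || k > n) stop("k must be in [2, number of compounds]")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  cv <- matrix(NA_real_, k, ncol(table),
               dimnames = list(NULL, colnames(table)))
  for (f in seq_len(k)) {
    sub <- table[fold != f, , drop = FALSE]
    z <- scale_for_srd(sub, scaling)
    ref <- reference_ranking(z)
    cr <- apply(z, 2L, rank_with_ties)
    cv[f, ] <- srd_normalize(
      apply(cr, 2L, srd_value, reference_ranks = ref), nrow(sub))
  }
  list(cv_pct = cv, fold = fold, k = k,
       median = apply(cv, 2L, stats::median),
       q1 = apply(cv, 2L, stats::quantile, probs = .25, names = FALSE),
       q3 = apply(cv, 2L, stats::quantile, probs = .75, names = FALSE))
}
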