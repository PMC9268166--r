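#' Synthetic descriptor dataset with a known informative subset
#'
#' Generates a compound x descriptor matrix with exchangeable block
#' correlation and a linear endpoint driven by a small random support:
#' `y = X[, support] %*% beta + noise`, with the noise standard deviation set
#' to `noise_frac` times the SD of the signal. Mirrors the scale of the
#' study: 27 compounds, a large candidate pool, 5 informative descriptors.
#'
#' @param n_compounds,n_descriptors,n_informative dataset dimensions.
#' @param noise_frac noise SD as a fraction of the signal SD (default 0.05).
#' @param correlation pairwise descriptor correlation in `[0, 1)`.
#' @param beta_range informative coefficients are drawn uniformly from
#'   `[-beta_range, -0.5] U [0.5, beta_range]` (bounded away from zero so the
#'   support is identifiable).
#' @param seed integer seed; the dataset is a pure function of it.
#' @return object of class `synthetic_dataset`: `X`, `y`, `true_support`,
#'   `true_beta`, `noise_sd`, `seed`.
#' @export
make_descriptor_dataset <- function(n_compounds = 27, n_descriptors = 100,
                                    n_informative = 5, noise_frac = 0.05,
                                    correlation = 0, beta_range = 2,
                                    seed = 1L) {
  if (n_informative > n_descriptors)
    stop("n_informative must be <= n_descriptors")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)")
  if (n_compounds < 3) stop("need at least 3 compounds")
  set.seed(seed)
  n <- n_compounds; p <- n_descriptors
  # exchangeable correlation: sqrt(rho) * shared factor + sqrt(1-rho) * own
  shared <- stats::rnorm(n)
  X <- sqrt(correlation) * matrix(shared, n, p) +
    sqrt(1 - correlation) * matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- sprintf("D%03d", seq_len(p))
  rownames(X) <- as.character(seq_len(n))
  support <- sort(sample.int(p, n_informative))
  beta <- numeric(p)
  mag <- stats::runif(n_informative, 0.5, beta_range)
  beta[support] <- mag * sample(c(-1, 1), n_informative, replace = TRUE)
  signal <- drop(X[, support, drop = FALSE] %*% beta[support])
  noise_sd <- noise_frac * stats::sd(signal)
  y <- signal + stats::rnorm(n, sd = noise_sd)
  structure(list(X = X, y = y, true_support = support,
                 true_beta = beta[support], noise_sd = noise_sd,
                 noise_frac = noise_frac, correlation = correlation,
                 seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic descriptor dataset: %d x %d, %d informative, noise SD %.3g (seed %d)\n",
              nrow(x$X), ncol(x$X), length(x$true_support), x$noise_sd,
              x$seed))
  cat("support:", paste(colnames(x$X)[x$true_support], collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic family of lipophilicity measures
#'
#' Emulates a compound x measure table in which every measure is a noisy
#' affine transform of one latent lipophilicity scale:
#' `measure_j = a_j + b_j * latent + N(0, noise_sd_j)` with `b_j > 0`.
#' Measures with small noise should rank compounds like the latent scale and
#' therefore attain small SRD values.
#'
#' @param n_compounds,n_measures table dimensions.
#' @param noise_sds per-measure noise SDs (length `n_measures`); default 0.3
#'   for every measure.
#' @param slopes,intercepts optional per-measure affine constants; slopes
#'   must be positive (drawn from U(0.5, 2) and N(0, 1) by default).
#' @param seed integer seed.
#' @return object of class `synthetic_lipo_table`: the realized `table`
#'   (a `lipo_table`), the `latent` scale, and the generating constants.
#' @export
make_lipo_table <- function(n_compounds = 27, n_measures = 12,
                            noise_sds = rep(0.3, n_measures),
                            slopes = NULL, intercepts = NULL, seed = 1L) {
  if (length(noise_sds) != n_measures)
    stop("noise_sds must have length n_measures")
  if (any(noise_sds < 0)) stop("noise_sds must be non-negative")
  set.seed(seed)
  latent <- stats::rnorm(n_compounds)
  if (is.null(slopes)) slopes <- stats::runif(n_measures, 0.5, 2)
  if (is.null(intercepts)) intercepts <- stats::rnorm(n_measures)
  if (any(slopes <= 0)) stop("slopes must be positive")
  vals <- vapply(seq_len(n_measures), function(j)
    intercepts[j] + slopes[j] * latent +
      stats::rnorm(n_compounds, sd = noise_sds[j]),
    numeric(n_compounds))
  colnames(vals) <- sprintf("M%02d", seq_len(n_measures))
  rownames(vals) <- as.character(seq_len(n_compounds))
  structure(list(table = lipo_table(vals, provenance = "synthetic"),
                 latent = latent, slopes = slopes,
                 intercepts = intercepts, noise_sds = noise_sds,
                 seed = seed),
            class = "synthetic_lipo_table")
}

#' @export
print.synthetic_lipo_table <- function(x, ...) {
  cat(sprintf("synthetic lipophilicity table: %d x %d (seed %d)\n",
              nrow(x$table), ncol(x$table), x$seed))
  cat("noise SDs:", paste(format(x$noise_sds, digits = 3),
                          collapse = " "), "\n")
  invisible(x)
}
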