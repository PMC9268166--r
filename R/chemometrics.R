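#' Pearson correlation matrix of the measures
#'
#' @param table compounds x measures matrix with >= 3 compounds and
#'   positive-variance columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  if (nrow(table) < 3L) stop("need at least 3 compounds")
  s <- apply(table, 2L, stats::sd)
  if (any(s == 0))
    stop("zero-variance column(s): ", paste(colnames(table)[s == 0],
                                            collapse = ", "))
  stats::cor(unclass(table))
}

#' Principal component analysis of standardized lipophilicity data
#'
#' PCA on the column-correlation structure: the input is autoscaled and the
#' principal axes obtained by singular value decomposition. Loadings signs
#' follow a deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param table compounds x measures matrix (raw scale; standardized
#'   internally).
#' @param n_components number of components to keep
#'   (`<= min(n - 1, p)`).
#' @return object of class `lipo_pca` with `scores`
#'   (compounds x components), `loadings` (measures x components), and
#'   `explained_variance_ratio`.
#' @export
lipo_pca <- function(table, n_components = 2L) {
  n <- nrow(table); p <- ncol(table)
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be in [1, ", kmax, "]")
  z <- standardize_columns(table)
  sv <- La.svd(unclass(z), nu = kmax, nv = kmax)
  d <- sv$d[seq_len(kmax)]
  load <- t(sv$vt)[, seq_len(kmax), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(kmax)) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) {
      load[, k] <- -load[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  scores <- sv$u[, seq_len(kmax), drop = FALSE] %*% diag(d, kmax)
  evr <- d^2 / sum(sv$d^2)
  keep <- seq_len(n_components)
  dimnames(load) <- list(colnames(table), paste0("PC", seq_len(kmax)))
  dimnames(scores) <- list(rownames(table), paste0("PC", seq_len(kmax)))
  structure(list(scores = scores[, keep, drop = FALSE],
                 loadings = load[, keep, drop = FALSE],
                 explained_variance_ratio = evr[keep],
                 all_singular_values = sv$d,
                 n_components = n_components),
            class = "lipo_pca")
}

#' @export
print.lipo_pca <- function(x, ...) {
  cat(sprintf("PCA of standardized lipophilicity data: %d component(s)\n",
              x$n_components))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
plot.lipo_pca <- function(x, which = c("scores", "loadings"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  if (ncol(m) < 2L) stop("need at least 2 components to plot")
  graphics::plot(m[, 1L], m[, 2L], type = "n",
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$explained_variance_ratio[1L]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$explained_variance_ratio[2L]), ...)
  graphics::text(m[, 1L], m[, 2L], labels = rownames(m))
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Ward/Euclidean hierarchical clustering of measures (or compounds)
#'
#' Measures are clustered as vectors over compounds after column
#' standardization (axis `"measures"`); compounds are clustered analogously
#' over the standardized measures (axis `"compounds"`). Linkage is Ward's
#' minimum-variance criterion on Euclidean distances.
#'
#' @param table compounds x measures matrix.
#' @param axis `"measures"` or `"compounds"`.
#' @return object of class `measure_dendrogram` wrapping the `hclust` merge
#'   structure.
#' @export
hierarchical_cluster <- function(table, axis = c("measures", "compounds")) {
  axis <- match.arg(axis)
  z <- standardize_columns(table)
  m <- if (axis == "measures") t(unclass(z)) else unclass(z)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, axis = axis, labels = rownames(m),
                 merge = hc$merge, height = hc$height),
            class = "measure_dendrogram")
}

#' @export
print.measure_dendrogram <- function(x, ...) {
  cat(sprintf("Ward/Euclidean dendrogram over %d %s (%d merges)\n",
              length(x$labels), x$axis, nrow(x$merge)))
  invisible(x)
}

#' @export
plot.measure_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = x$axis, sub = "",
                 main = "Ward / Euclidean clustering", ...)
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram a `measure_dendrogram`.
#' @param k number of clusters, `1 <= k <=` number of items.
#' @return integer cluster label per item, named.
#' @export
cluster_membership <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  stats::cutree(dendrogram$hclust, k = k)
}
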