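# Independent brute-force oracles used across the suite.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# literal-enumeration SRD null distribution against the identity reference
crrn_enumerate <- function(n) {
  perms <- all_perms(n)
  d <- apply(perms, 1L, function(p) sum(abs(p - seq_len(n))))
  table(d) / nrow(perms)
}

# literal 2^n enumeration of the Wilcoxon signed-rank two-sided p-value
wilcoxon_enumerate <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# Lance-Williams Ward recursion on squared Euclidean distances; returns the
# merge heights (on the distance scale, ward.D2 convention) and the
# membership vector at k clusters
ward_oracle <- function(X, k = NULL) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  size <- rep(1, n)
  active <- seq_len(n)
  membership <- seq_len(n)
  heights <- numeric(0)
  D2cur <- D2
  diag(D2cur) <- Inf
  # Ward merge cost between clusters i,j is (ni*nj/(ni+nj)) * ||ci - cj||^2;
  # maintain it via the Lance-Williams update on the cost matrix
  cost <- D2cur / 2
  for (step in seq_len(n - 1L)) {
    idx <- which(cost == min(cost[active, active]), arr.ind = TRUE)[1L, ]
    i <- min(idx); j <- max(idx)
    heights <- c(heights, sqrt(2 * cost[i, j]))
    membership[membership == j] <- i
    for (m in setdiff(active, c(i, j))) {
      ni <- size[i]; nj <- size[j]; nm <- size[m]
      new_cost <- ((ni + nm) * cost[i, m] + (nj + nm) * cost[j, m] -
                     nm * cost[i, j]) / (ni + nj + nm)
      cost[i, m] <- cost[m, i] <- new_cost
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
    cost[j, ] <- cost[, j] <- Inf
  }
  memb_k <- NULL
  if (!is.null(k)) {
    # recompute memberships stopping at n - k merges
    membership <- seq_len(n)
    size <- rep(1, n); active <- seq_len(n)
    cost <- D2 / 2; diag(cost) <- Inf
    nm_steps <- n - k
    for (step in seq_len(nm_steps)) {
      idx <- which(cost == min(cost[active, active]), arr.ind = TRUE)[1L, ]
      i <- min(idx); j <- max(idx)
      membership[membership == j] <- i
      for (m in setdiff(active, c(i, j))) {
        ni <- size[i]; nj <- size[j]; nm <- size[m]
        cost[i, m] <- cost[m, i] <-
          ((ni + nm) * cost[i, m] + (nj + nm) * cost[j, m] -
             nm * cost[i, j]) / (ni + nj + nm)
      }
      size[i] <- size[i] + size[j]
      active <- setdiff(active, j)
      cost[j, ] <- cost[, j] <- Inf
    }
    memb_k <- match(membership, unique(membership))
  }
  list(heights = sort(heights), membership = memb_k)
}

# direct transcription of the external-validation formula battery
validation_oracle <- function(yo_tr, yp_tr, yo_e, yp_e) {
  ntr <- length(yo_tr); ne <- length(yo_e)
  mtr <- mean(yo_tr); me <- mean(yo_e); mpe <- mean(yp_e)
  list(
    r2 = 1 - sum((yo_tr - yp_tr)^2) / sum((yo_tr - mtr)^2),
    q2_f1 = 1 - sum((yo_e - yp_e)^2) / sum((yo_e - mtr)^2),
    q2_f2 = 1 - sum((yo_e - yp_e)^2) / sum((yo_e - me)^2),
    q2_f3 = 1 - (sum((yo_e - yp_e)^2) / ne) / (sum((yo_tr - mtr)^2) / ntr),
    rmse_p = sqrt(sum((yo_e - yp_e)^2) / ne),
    ccc = 2 * sum((yo_e - me) * (yp_e - mpe)) /
      (sum((yo_e - me)^2) + sum((yp_e - mpe)^2) + ne * (me - mpe)^2))
}

# small random lipo table for quick tests
random_table <- function(n = 6, p = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(as.character(seq_len(n)),
                              paste0("M", seq_len(p))))
  m
}
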