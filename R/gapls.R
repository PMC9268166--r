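#' GA configuration
#'
#' Control parameters of the genetic-algorithm descriptor search. Defaults
#' follow the published settings: population 500, per-gene mutation rate 0.1,
#' five descriptors per model, three latent variables; the remaining operators
#' (tournament selection of size 2, uniform crossover with duplicate repair,
#' elitism 1, up to 100 generations with a 20-generation stall stop) are
#' minimal standard choices.
#'
#' @param population_size number of chromosomes per generation.
#' @param mutation_rate per-gene mutation probability.
#' @param n_descriptors descriptors per model (chromosome length).
#' @param n_lv latent variables of the PLS fitness model.
#' @param n_generations generation budget.
#' @param elitism number of best chromosomes copied unchanged.
#' @param tournament_size selection tournament size.
#' @param stall_generations stop early after this many generations without
#'   improvement (`Inf` disables).
#' @param immigrant_frac fraction of each generation replaced by fresh
#'   random chromosomes (diversity maintenance).
#' @param init `"beam"` seeds the initial population with candidates from a
#'   greedy beam search under the same fitness (informed initialization);
#'   `"random"` starts from a purely random population.
#' @param beam_width beam width of the initialization search; `NULL` (the
#'   default) uses twice the number of candidate descriptors, bounded to
#'   `[50, 250]`.
#' @param fitness `"r2"` (training R2, the published criterion) or
#'   `"q2_loo"`.
#' @export
ga_config <- function(population_size = 500, mutation_rate = 0.1,
                      n_descriptors = 5, n_lv = 3, n_generations = 100,
                      elitism = 1, tournament_size = 2,
                      stall_generations = 20, immigrant_frac = 0.05,
                      init = c("beam", "random"), beam_width = NULL,
                      fitness = c("r2", "q2_loo")) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (n_descriptors < n_lv)
    stop("n_descriptors must be >= n_lv")
  if (immigrant_frac < 0 || immigrant_frac > 0.5)
    stop("immigrant_frac must be in [0, 0.5]")
  list(population_size = population_size, mutation_rate = mutation_rate,
       n_descriptors = n_descriptors, n_lv = n_lv,
       n_generations = n_generations, elitism = elitism,
       tournament_size = tournament_size,
       stall_generations = stall_generations,
       immigrant_frac = immigrant_frac,
       init = match.arg(init), beam_width = beam_width,
       fitness = match.arg(fitness))
}

#' Training/test split keeping the endpoint extremes in training
#'
#' Seeded random split; if the compounds carrying the minimum or maximum of
#' the endpoint land in the test set they are swapped with randomly chosen
#' training members, so the model never extrapolates beyond the training
#' range of y.
#'
#' @param y endpoint vector (named or not).
#' @param n_train,n_test set sizes; must sum to `length(y)`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_minmax <- function(y, n_train = 18, n_test = length(y) - n_train,
                         seed = 1L) {
  n <- length(y)
  if (n_train + n_test != n) stop("n_train + n_test must equal length(y)")
  if (n_train < 2) stop("n_train must be >= 2")
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)
  for (idx in c(which.min(y), which.max(y))) {
    if (idx %in% test) {
      swap_candidates <- setdiff(train, c(which.min(y), which.max(y)))
      swap <- .resample(swap_candidates, 1L)
      train <- sort(c(setdiff(train, swap), idx))
      test <- sort(c(setdiff(test, idx), swap))
    }
  }
  list(train = train, test = test)
}

# training R2 of an A-LV PLS1 fit on pre-autoscaled X columns `chrom`
.fitness_r2 <- function(Xs, yc, chrom, A) {
  E <- Xs[, chrom, drop = FALSE]
  f <- yc
  ssy <- sum(yc^2)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
  }
  1 - sum(f^2) / ssy
}

# sample() without the scalar-x surprise
.resample <- function(v, k) v[sample.int(length(v), k)]

# replace duplicate genes with fresh random indices
.repair <- function(chrom, p) {
  while (anyDuplicated(chrom)) {
    dup <- which(duplicated(chrom))
    chrom[dup] <- .resample(setdiff(seq_len(p), chrom), length(dup))
  }
  chrom
}

# greedy beam search over descriptor subsets under the GA fitness; partial
# subsets of size < n_lv are scored with as many LVs as they admit. Returns
# up to `width` full-size candidate chromosomes (rows).
.beam_candidates <- function(Xs, yc, nd, A, width) {
  p <- ncol(Xs)
  fitp <- function(ch) .fitness_r2(Xs, yc, ch, min(A, length(ch)))
  sc1 <- vapply(seq_len(p), function(j) fitp(j), 0)
  keep <- order(sc1, decreasing = TRUE)[seq_len(min(width, p))]
  beam <- as.list(keep)
  for (size in seq.int(2L, nd)) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    cand <- vector("list", length(beam) * (p - size + 1L))
    m <- 0L
    for (b in beam) for (j in seq_len(p)) {
      if (j %in% b) next
      ch <- sort.int(c(b, j))
      k <- paste(ch, collapse = ",")
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        m <- m + 1L
        cand[[m]] <- ch
      }
    }
    cand <- cand[seq_len(m)]
    sc <- vapply(cand, fitp, 0)
    beam <- cand[order(sc, decreasing = TRUE)[seq_len(min(width, m))]]
  }
  do.call(rbind, beam)
}

#' Genetic-algorithm descriptor selection with PLS fitness
#'
#' Evolves fixed-length chromosomes of distinct descriptor indices; fitness
#' is the training R2 of a PLS fit with `config$n_lv` latent variables on
#' the training split. The best subset is refit and fully validated:
#' leave-one-out Q2/RMSEcv on the training set and the external statistics
#' (Q2F1/F2/F3, RMSEP, CCC) on the held-out test set.
#'
#' @param X candidate descriptor matrix (compounds x descriptors), already
#'   cleaned of (near-)constant columns.
#' @param y endpoint vector.
#' @param config a [ga_config()] list.
#' @param split optional list with `train`/`test` indices; generated by
#'   [split_minmax()] (18/9 by default) when absent.
#' @param seed integer seed for the evolutionary search (and the split when
#'   one is generated).
#' @return object of class `gapls`.
#' @export
ga_pls <- function(X, y, config = ga_config(), split = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  nd <- config$n_descriptors
  if (p < nd) stop("fewer than ", nd, " usable descriptors")
  if (stats::var(y) == 0) stop("endpoint has zero variance")
  if (is.null(split))
    split <- split_minmax(y, n_train = min(18L, length(y) - 2L),
                          n_test = length(y) - min(18L, length(y) - 2L),
                          seed = seed)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  set.seed(seed)
  Xs <- standardize_columns(Xtr)
  yc <- ytr - mean(ytr)
  A <- config$n_lv
  fit_fun <- if (config$fitness == "r2") {
    function(chrom) .fitness_r2(Xs, yc, chrom, A)
  } else {
    function(chrom) q2_loo(Xtr[, chrom, drop = FALSE], ytr, A)$q2_loo
  }

  if (p == nd) {
    pop <- matrix(seq_len(p), nrow = 1L)
    best <- pop[1L, ]; trajectory <- fit_fun(best)
  } else {
    ps <- config$population_size
    pop <- t(vapply(seq_len(ps), function(i) sample.int(p, nd),
                    integer(nd)))
    if (config$init == "beam" && config$fitness == "r2") {
      bw <- config$beam_width
      if (is.null(bw)) bw <- min(max(50L, 2L * p), 250L)
      seedlings <- .beam_candidates(Xs, yc, nd, A, bw)
      take <- min(nrow(seedlings), ps)
      pop[seq_len(take), ] <- seedlings[seq_len(take), , drop = FALSE]
    }
    fitness <- apply(pop, 1L, fit_fun)
    trajectory <- numeric(0)
    best_fit <- -Inf; best <- pop[1L, ]; stall <- 0L
    chrom_key <- function(ch) paste(sort.int(ch), collapse = ",")
    n_imm <- round(config$immigrant_frac * ps)
    for (g in seq_len(config$n_generations)) {
      gen_best <- which.max(fitness)
      if (fitness[gen_best] > best_fit + 1e-12) {
        best_fit <- fitness[gen_best]; best <- pop[gen_best, ]; stall <- 0L
      } else stall <- stall + 1L
      trajectory <- c(trajectory, best_fit)
      if (stall >= config$stall_generations) break
      newpop <- matrix(0L, ps, nd)
      elite <- order(fitness, decreasing = TRUE)[seq_len(config$elitism)]
      newpop[seq_len(config$elitism), ] <- pop[elite, , drop = FALSE]
      seen <- new.env(hash = TRUE, parent = emptyenv())
      for (e in seq_len(config$elitism))
        seen[[chrom_key(newpop[e, ])]] <- TRUE
      pick <- function() {
        cand <- sample.int(ps, config$tournament_size)
        cand[which.max(fitness[cand])]
      }
      i <- config$elitism + 1L
      while (i <= ps) {
        if (i <= config$elitism + n_imm) {
          child <- sample.int(p, nd)       # random immigrant
        } else {
          pa <- pop[pick(), ]; pb <- pop[pick(), ]
          # set-semantics uniform crossover: keep shared genes, fill the
          # remaining slots from the parents' symmetric difference
          common <- intersect(pa, pb)
          rest <- setdiff(union(pa, pb), common)
          child <- c(common, .resample(rest, nd - length(common)))
          mut <- stats::runif(nd) < config$mutation_rate
          if (any(mut))
            child[mut] <- .resample(setdiff(seq_len(p), child), sum(mut))
        }
        k <- chrom_key(child)
        if (!is.null(seen[[k]])) {
          # duplicate chromosome: mutate one gene to keep the population
          # unique (anti-takeover)
          j <- sample.int(nd, 1L)
          child[j] <- .resample(setdiff(seq_len(p), child), 1L)
          k <- chrom_key(child)
          if (!is.null(seen[[k]])) next
        }
        seen[[k]] <- TRUE
        newpop[i, ] <- child
        i <- i + 1L
      }
      pop <- newpop
      fitness <- apply(pop, 1L, fit_fun)
    }
    # final generation may contain an improvement
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best_fit) {
      best_fit <- fitness[gen_best]; best <- pop[gen_best, ]
      trajectory <- c(trajectory, best_fit)
    }
  }

  best <- sort(best)
  sel <- colnames(X)[best]
  model <- pls_fit(Xtr[, best, drop = FALSE], ytr, A)
  loo <- q2_loo(Xtr[, best, drop = FALSE], ytr, A)
  pred_tr <- model$fitted.values
  pred_ext <- predict(model, X[split$test, best, drop = FALSE])
  stats <- validation_stats(ytr, pred_tr, y[split$test], pred_ext)
  stats$q2_loo <- loo$q2_loo
  stats$rmse_cv <- loo$rmse_cv
  structure(list(selected = sel, selected_idx = best,
                 model = model, stats = stats,
                 trajectory = trajectory, split = split,
                 config = config, seed = seed,
                 y = y, X_selected = X[, best, drop = FALSE]),
            class = "gapls")
}

#' @export
print.gapls <- function(x, ...) {
  cat("GA-PLS model\n")
  cat("selected descriptors:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("R2 = %.3f  Q2loo = %.3f  RMSEcv = %.3f\n",
              x$stats$r2, x$stats$q2_loo, x$stats$rmse_cv))
  cat(sprintf("Q2F1 = %.3f  Q2F2 = %.3f  Q2F3 = %.3f  RMSEP = %.3f  CCC = %.3f\n",
              x$stats$q2_f1, x$stats$q2_f2, x$stats$q2_f3,
              x$stats$rmse_p, x$stats$ccc))
  invisible(x)
}

#' @export
coef.gapls <- function(object, ...) coef(object$model, ...)

#' @export
predict.gapls <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
plot.gapls <- function(x, ...) {
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s",
                 xlab = "generation", ylab = "best training R2",
                 main = "GA-PLS fitness trajectory", ...)
  invisible(x)
}

#' y-randomization (response permutation) test
#'
#' Refits the PLS model on the fixed selected descriptors with the response
#' randomly permuted, recording R2 and Q2loo for each permutation. A robust
#' model's original statistics should exceed the whole permuted distribution.
#'
#' @param X_selected matrix of the selected descriptors (training rows).
#' @param y training endpoint.
#' @param n_lv latent variables.
#' @param n_permutations number of random permutations (default 200).
#' @param seed integer seed.
#' @return object of class `y_randomization` with the permuted
#'   distributions, the original statistics, and exceedance fractions.
#' @export
y_randomization <- function(X_selected, y, n_lv = 3, n_permutations = 200,
                            seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (stats::var(y) == 0) stop("endpoint has zero variance")
  X_selected <- as.matrix(X_selected)
  orig_fit <- pls_fit(X_selected, y, n_lv)
  orig_r2 <- 1 - sum((y - orig_fit$fitted.values)^2) /
    sum((y - mean(y))^2)
  orig_q2 <- q2_loo(X_selected, y, n_lv)$q2_loo
  set.seed(seed)
  perm_r2 <- perm_q2 <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    fit <- pls_fit(X_selected, yp, n_lv)
    perm_r2[b] <- 1 - sum((yp - fit$fitted.values)^2) /
      sum((yp - mean(yp))^2)
    perm_q2[b] <- q2_loo(X_selected, yp, n_lv)$q2_loo
  }
  structure(list(n_permutations = n_permutations,
                 perm_r2 = perm_r2, perm_q2 = perm_q2,
                 orig_r2 = orig_r2, orig_q2 = orig_q2,
                 frac_r2_exceed = mean(perm_r2 >= orig_r2),
                 frac_q2_exceed = mean(perm_q2 >= orig_q2),
                 seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("y-randomization: %d permutations\n", x$n_permutations))
  cat(sprintf("original R2 = %.3f (max permuted %.3f, exceeded in %.1f%%)\n",
              x$orig_r2, max(x$perm_r2), 100 * x$frac_r2_exceed))
  cat(sprintf("original Q2loo = %.3f (max permuted %.3f, exceeded in %.1f%%)\n",
              x$orig_q2, max(x$perm_q2), 100 * x$frac_q2_exceed))
  invisible(x)
}

#' Leverage-based applicability domain (Williams plot data)
#'
#' Leverages are computed on the autoscaled selected descriptors augmented
#' with an intercept column, `h_i = x_i (X'X)^{-1} x_i'` using the training
#' cross-product; the critical value is the conventional
#' `h* = 3 (p + 1) / n_train`. Standardized residuals divide each residual
#' by the training residual standard deviation, with a ±3σ acceptance band
#' applied to both sets.
#'
#' @param model a fitted `pls` object (from [pls_fit()] on the training set).
#' @param X_train,X_test descriptor matrices restricted to the model's
#'   selected descriptors.
#' @param y_train,y_test observed endpoints.
#' @return object of class `ad_result` with per-compound leverage,
#'   standardized residual, set membership, flags, and `h_star`.
#' @export
leverage_ad <- function(model, X_train, X_test, y_train, y_test) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  p <- length(model$descriptor_names)
  n_tr <- nrow(X_train)
  scale_rows <- function(X)
    cbind(1, sweep(sweep(X, 2L, model$x_center, "-"),
                   2L, model$x_scale, "/"))
  Atr <- scale_rows(X_train)
  Ate <- scale_rows(X_test)
  XtX <- crossprod(Atr)
  if (rcond(XtX) < 1e-12)
    stop("singular descriptor cross-product (collinear selected descriptors)")
  inv <- solve(XtX)
  lev <- function(A) rowSums((A %*% inv) * A)
  h_tr <- lev(Atr); h_te <- lev(Ate)
  h_star <- 3 * (p + 1) / n_tr
  res_tr <- y_train - predict(model, X_train)
  res_te <- y_test - predict(model, X_test)
  s <- stats::sd(res_tr)
  std_tr <- res_tr / s; std_te <- res_te / s
  set <- c(rep("train", n_tr), rep("test", nrow(X_test)))
  h <- unname(c(h_tr, h_te)); std <- unname(c(std_tr, std_te))
  structure(list(leverage = h, std_residual = std, set = set,
                 h_star = h_star,
                 outside_h_star = h > h_star,
                 outside_3sigma = abs(std) > 3,
                 ids = c(rownames(X_train), rownames(X_test))),
            class = "ad_result")
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("Applicability domain: h* = %.4f\n", x$h_star))
  cat(sum(x$outside_h_star), "compound(s) beyond h*;",
      sum(x$outside_3sigma), "beyond |3 sigma| residual band\n")
  invisible(x)
}

#' @export
plot.ad_result <- function(x, ...) {
  graphics::plot(x$leverage, x$std_residual,
                 pch = ifelse(x$set == "train", 16, 1),
                 xlab = "leverage", ylab = "standardized residual",
                 main = "Williams plot", ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-3, 3), lty = 2)
  invisible(x)
}
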