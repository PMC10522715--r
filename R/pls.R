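## PLS-SVD between the feature matrix and the micro-architectural map
## set, with spin-permutation significance, bootstrap loading reliability
## and distance-dependent cross-validation.

zscore_cols <- function(M, label) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop(sprintf("constant column in %s: %s", label,
                 paste(colnames(M)[bad], collapse = ", ")))
  list(z = sweep(sweep(M, 2, mu), 2, sdv, "/"), mean = mu, sd = sdv)
}

pls_core <- function(Xz, Yz) {
  n <- nrow(Xz)
  R <- crossprod(Xz, Yz) / (n - 1)      # entries are Pearson correlations
  sv <- svd(R)
  ## sign convention: largest-|V| element of each LV is positive
  for (c in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, c]))
    if (sv$v[i, c] < 0) {
      sv$v[, c] <- -sv$v[, c]
      sv$u[, c] <- -sv$u[, c]
    }
  }
  list(U = sv$u, V = sv$v, S = sv$d, R = R)
}

#' Partial least squares between features and maps
#'
#' Z-scores both matrices column-wise, forms the cross-correlation matrix
#' `R = X'Y / (n - 1)` and applies a singular value decomposition
#' `R = U S V'`. Each latent variable pairs a weighted combination of
#' time-series features (left singular vector) with one of
#' micro-architectural maps (right singular vector); effect sizes are
#' `eta_i = s_i^2 / sum_j s_j^2`. Brain scores project the z-scored data
#' onto the weights (XU, YV); loadings are the Pearson correlations
#' between each original column and its side's score map.
#'
#' @param X regions x features matrix or `feature_matrix`.
#' @param Y regions x maps matrix or `brain_maps`.
#' @return A `pls_map` object with `U`, `V`, `S`, `eta`, `scores_X`,
#'   `scores_Y`, `loadings_X`, `loadings_Y`, and the z-scoring statistics
#'   used (for projecting new data).
#' @export
fit_pls <- function(X, Y) {
  Xm <- as_feature_values(X)
  Ym <- as.matrix(Y)
  check_shared_regions(rownames(Xm), rownames(Ym), "X and Y")
  zx <- zscore_cols(Xm, "X")
  zy <- zscore_cols(Ym, "Y")
  core <- pls_core(zx$z, zy$z)
  scores_X <- zx$z %*% core$U
  scores_Y <- zy$z %*% core$V
  loadings_X <- cor(Xm, scores_X)
  loadings_Y <- cor(Ym, scores_Y)
  structure(list(U = core$U, V = core$V, S = core$S,
                 eta = core$S^2 / sum(core$S^2),
                 scores_X = scores_X, scores_Y = scores_Y,
                 loadings_X = loadings_X, loadings_Y = loadings_Y,
                 x_mean = zx$mean, x_sd = zx$sd,
                 y_mean = zy$mean, y_sd = zy$sd,
                 n = nrow(Xm), region_id = rownames(Xm),
                 feature_name = colnames(Xm), map_name = colnames(Ym)),
            class = "pls_map")
}

#' @export
print.pls_map <- function(x, ...) {
  cat(sprintf("PLS mapping: %d regions, %d features x %d maps\n",
              x$n, length(x$feature_name), length(x$map_name)))
  k <- min(3, length(x$S))
  for (i in seq_len(k)) {
    r <- cor(x$scores_X[, i], x$scores_Y[, i], method = "spearman")
    cat(sprintf("  LV%d: singular value %.3f, effect size %.1f%%, score r_s %.2f\n",
                i, x$S[i], 100 * x$eta[i], r))
  }
  invisible(x)
}

#' @export
summary.pls_map <- function(object, ...) {
  print(object)
  cat("Top |loading| maps on LV1:\n")
  l <- object$loadings_Y[, 1]
  print(round(sort(l, decreasing = TRUE), 3))
  invisible(object)
}

#' Spin-permutation significance of PLS latent variables
#'
#' Rearranges the rows of Y by each spin assignment, refits the PLS, and
#' compares the observed singular values with the permuted null
#' distribution: `p_i = (1 + #{s_i^null >= s_i}) / (n_spins + 1)`
#' (one-sided, since singular values are non-negative). The maps side is
#' spun because it is the spatially smooth side; X is held fixed.
#'
#' @param X,Y the matrices passed to [fit_pls()].
#' @param spins a `spin_set` on the shared geometry.
#' @param fit optional prefitted `pls_map` (refitted if missing).
#' @return list with `p_spin` (per LV), `null_S` (spins x LV matrix) and
#'   `n_failed` permutations.
#' @export
pls_significance <- function(X, Y, spins, fit = NULL) {
  if (is.null(fit)) fit <- fit_pls(X, Y)
  Xz <- zscore_cols(as_feature_values(X), "X")$z
  Yz <- zscore_cols(as.matrix(Y), "Y")$z
  ns <- nrow(spins$perms)
  null_S <- matrix(NA_real_, ns, length(fit$S))
  n_failed <- 0L
  for (i in seq_len(ns)) {
    res <- try(svd(crossprod(Xz, Yz[spins$perms[i, ], , drop = FALSE]) /
                     (fit$n - 1), nu = 0, nv = 0)$d, silent = TRUE)
    if (inherits(res, "try-error")) { n_failed <- n_failed + 1L; next }
    null_S[i, ] <- res
  }
  ok <- !is.na(null_S[, 1])
  p <- vapply(seq_along(fit$S), function(i)
    (1 + sum(null_S[ok, i] >= fit$S[i])) / (sum(ok) + 1), 0)
  list(p_spin = p, null_S = null_S, n_failed = n_failed)
}

#' Bootstrap confidence intervals for PLS loadings
#'
#' Resamples regions (rows of X and Y jointly) with replacement,
#' recomputes the z-scoring and the PLS on each resample, aligns the
#' resampled singular vectors to the original solution by orthogonal
#' Procrustes on V (absorbing sign flips and axis rotations), and pools
#' the resampled loadings into percentile 95% confidence intervals. A
#' loading is reliable when its CI excludes zero. Resamples that produce
#' a constant column are discarded and redrawn.
#'
#' @param X,Y the matrices passed to [fit_pls()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param fit optional prefitted `pls_map`.
#' @param level confidence level (default 0.95).
#' @return list with `ci_X` / `ci_Y` (arrays var x LV x {lo, hi}),
#'   `reliable_X` / `reliable_Y` (CI excludes 0) and `n_redrawn`.
#' @export
bootstrap_loadings <- function(X, Y, n_boot = 1000L, seed = 1L, fit = NULL,
                               level = 0.95) {
  Xm <- as_feature_values(X)
  Ym <- as.matrix(Y)
  if (is.null(fit)) fit <- fit_pls(Xm, Ym)
  n <- nrow(Xm)
  m <- length(fit$S)
  bx <- array(NA_real_, c(ncol(Xm), m, n_boot))
  by <- array(NA_real_, c(ncol(Ym), m, n_boot))
  n_redrawn <- 0L
  with_seed(offspring_seed(seed, "bootstrap"), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- Xm[idx, , drop = FALSE]
        Yb <- Ym[idx, , drop = FALSE]
        if (all(apply(Xb, 2, sd) > 0) && all(apply(Yb, 2, sd) > 0)) break
        n_redrawn <- n_redrawn + 1L
      }
      zx <- zscore_cols(Xb, "X"); zy <- zscore_cols(Yb, "Y")
      core <- pls_core(zx$z, zy$z)
      rot <- procrustes_align(fit$V, core$V)$rotation
      Ub <- core$U %*% rot
      Vb <- core$V %*% rot
      bx[, , b] <- cor(Xb, zx$z %*% Ub)
      by[, , b] <- cor(Yb, zy$z %*% Vb)
    }
  })
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- function(arr, names_v) {
    lo <- apply(arr, c(1, 2), quantile, probs = qs[1], na.rm = TRUE)
    hi <- apply(arr, c(1, 2), quantile, probs = qs[2], na.rm = TRUE)
    out <- array(c(lo, hi), c(nrow(lo), ncol(lo), 2),
                 dimnames = list(names_v, paste0("LV", seq_len(ncol(lo))),
                                 c("lo", "hi")))
    out
  }
  ci_X <- ci(bx, colnames(Xm))
  ci_Y <- ci(by, colnames(Ym))
  list(ci_X = ci_X, ci_Y = ci_Y,
       reliable_X = ci_X[, , "lo"] > 0 | ci_X[, , "hi"] < 0,
       reliable_Y = ci_Y[, , "lo"] > 0 | ci_Y[, , "hi"] < 0,
       n_redrawn = n_redrawn)
}

#' Distance-dependent cross-validation of PLS brain scores
#'
#' For each split a distinct seed region is drawn; the 75% of regions
#' closest to it in Euclidean (chord) distance form the training set and
#' the remaining distant 25% the test set. The PLS is fitted on the
#' training rows (z-scored with training statistics), the test rows are
#' z-scored with the training means/SDs and projected onto the training
#' singular vectors, and the Spearman correlation between LV1 feature and
#' map scores is reported for both sets.
#'
#' @param X,Y the matrices passed to [fit_pls()].
#' @param geom a `parcel_geometry` aligned with the rows.
#' @param train_frac fraction of regions in the training set.
#' @param n_splits number of splits (at most R - 1).
#' @param seed integer seed.
#' @return data.frame with `split`, `seed_region`, `train_rs`, `test_rs`;
#'   degenerate splits (constant training column) carry NA and are
#'   counted in attribute `n_failed`.
#' @export
distance_cv <- function(X, Y, geom, train_frac = 0.75, n_splits = 99L,
                        seed = 1L) {
  Xm <- as_feature_values(X)
  Ym <- as.matrix(Y)
  stopifnot(inherits(geom, "parcel_geometry"))
  R <- nrow(Xm)
  if (R < 8) stop("need at least 8 regions")
  if (n_splits > R - 1) stop("n_splits must be <= R - 1")
  xyz <- geometry_xyz(geom)
  check_shared_regions(rownames(Xm), geom$region_id, "X and geometry")
  ntrain <- ceiling(train_frac * R)
  out <- data.frame(split = seq_len(n_splits), seed_region = NA_character_,
                    train_rs = NA_real_, test_rs = NA_real_)
  n_failed <- 0L
  with_seed(offspring_seed(seed, "distance_cv"), {
    seeds <- sample.int(R, n_splits, replace = FALSE)
    for (s in seq_len(n_splits)) {
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[seeds[s], ])^2))
      ord <- order(d)                    # ties broken by region index
      tr <- ord[seq_len(ntrain)]
      te <- ord[(ntrain + 1):R]
      res <- try({
        zx <- zscore_cols(Xm[tr, , drop = FALSE], "train X")
        zy <- zscore_cols(Ym[tr, , drop = FALSE], "train Y")
        core <- pls_core(zx$z, zy$z)
        sx_tr <- zx$z %*% core$U[, 1]
        sy_tr <- zy$z %*% core$V[, 1]
        xte <- sweep(sweep(Xm[te, , drop = FALSE], 2, zx$mean), 2, zx$sd, "/")
        yte <- sweep(sweep(Ym[te, , drop = FALSE], 2, zy$mean), 2, zy$sd, "/")
        sx_te <- xte %*% core$U[, 1]
        sy_te <- yte %*% core$V[, 1]
        c(cor(sx_tr, sy_tr, method = "spearman"),
          cor(sx_te, sy_te, method = "spearman"))
      }, silent = TRUE)
      if (inherits(res, "try-error")) { n_failed <- n_failed + 1L; next }
      out$seed_region[s] <- geom$region_id[seeds[s]]
      out$train_rs[s] <- res[1]
      out$test_rs[s] <- res[2]
    }
  })
  attr(out, "n_failed") <- n_failed
  out
}
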