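## PCA gradients of the feature matrix, loading inference, map
## contextualization, and sensitivity procedures.

as_feature_values <- function(F) {
  if (inherits(F, "feature_matrix")) valid_features(F) else as.matrix(F)
}

#' Principal-component gradients of the feature matrix
#'
#' Column-centered PCA of the (normalized) valid feature columns. Scores
#' are the data projected on the component weights. Sign convention: each
#' component is flipped, if needed, so that its score map correlates
#' positively with its top-|weight| feature.
#'
#' @param F a `feature_matrix` (valid columns are used) or numeric matrix.
#' @return A `pca_gradients` object: `weights` (features x components),
#'   `scores` (regions x components), `var_explained` (fraction per
#'   component).
#' @export
run_pca <- function(F) {
  X <- as_feature_values(F)
  if (nrow(X) < 2) stop("need at least 2 regions")
  if (!all(is.finite(X))) stop("non-finite entries in the feature matrix")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  W <- pc$rotation
  S <- pc$x
  for (c in seq_len(ncol(W))) {
    top <- which.max(abs(W[, c]))
    r <- suppressWarnings(cor(S[, c], X[, top]))
    if (is.finite(r) && r < 0) {
      W[, c] <- -W[, c]
      S[, c] <- -S[, c]
    }
  }
  structure(list(weights = W, scores = S, var_explained = ve,
                 center = pc$center,
                 region_id = rownames(X), feature_name = colnames(X)),
            class = "pca_gradients")
}

#' @export
print.pca_gradients <- function(x, ...) {
  cat(sprintf("PCA gradients: %d regions x %d features\n",
              nrow(x$scores), nrow(x$weights)))
  k <- min(5, length(x$var_explained))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[1:k]),
            collapse = ", "),
      if (length(x$var_explained) > k) "..." else "", "\n")
  invisible(x)
}

#' Feature loadings on a principal component
#'
#' Pearson correlation between each feature column and the component's
#' score map, with a two-tailed spin permutation p-value per feature and
#' FDR correction across features. Constant features are excluded and
#' flagged.
#'
#' @param F a `feature_matrix` or matrix.
#' @param pca a `pca_gradients` from [run_pca()].
#' @param spins a `spin_set`.
#' @param component component index (default 1).
#' @param q FDR level.
#' @return data.frame with `feature`, `r`, `p_spin`, `p_fdr`,
#'   `significant`, `excluded`.
#' @export
pc_loadings <- function(F, pca, spins, component = 1L, q = 0.05) {
  X <- as_feature_values(F)
  if (component > ncol(pca$scores)) stop("component does not exist")
  score <- pca$scores[, component]
  out <- data.frame(feature = colnames(X), r = NA_real_, p_spin = NA_real_,
                    p_fdr = NA_real_, significant = FALSE, excluded = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    if (sd(X[, j]) == 0) { out$excluded[j] <- TRUE; next }
    sp <- spin_pvalue(score, X[, j], spins,
                      stat = function(a, b) cor(a, b), tail = "two")
    out$r[j] <- sp$observed
    out$p_spin[j] <- sp$p
  }
  ok <- !out$excluded
  fdr <- fdr_correct(out$p_spin[ok], q)
  out$p_fdr[ok] <- fdr$p_adjusted
  out$significant[ok] <- fdr$rejected
  out
}

#' Contextualize a score map against reference maps
#'
#' Spearman correlation of a regional score map with each reference map,
#' two-tailed spin p-values and FDR correction across maps.
#'
#' @param scores numeric regional map (e.g. PC1 brain scores).
#' @param refs a `brain_maps` set of reference maps.
#' @param spins a `spin_set`.
#' @param q FDR level.
#' @return data.frame with `map`, `r_s`, `p_spin`, `p_fdr`, `significant`.
#' @export
contextualize <- function(scores, refs, spins, q = 0.05) {
  refs <- as.matrix(refs)
  if (ncol(refs) == 0) stop("no reference maps supplied")
  out <- data.frame(map = colnames(refs), r_s = NA_real_,
                    p_spin = NA_real_, p_fdr = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(refs))) {
    sp <- spin_pvalue(scores, refs[, j], spins, tail = "two")
    out$r_s[j] <- sp$observed
    out$p_spin[j] <- sp$p
  }
  fdr <- fdr_correct(out$p_spin, q)
  out$p_fdr <- fdr$p_adjusted
  out$significant <- fdr$rejected
  out
}

#' Drop features associated with signal-to-noise ratio
#'
#' Removes feature columns whose Pearson correlation with the SNR map is
#' significant under the spin null at uncorrected p < alpha (deliberately
#' conservative feature selection: no multiple-comparison correction, so
#' more features are removed).
#'
#' @param F a `feature_matrix`.
#' @param snr numeric regional SNR map.
#' @param spins a `spin_set`.
#' @param alpha uncorrected removal threshold (default 0.05).
#' @return A reduced `feature_matrix`; attribute `dropped` lists removed
#'   feature names.
#' @export
snr_feature_filter <- function(F, snr, spins, alpha = 0.05) {
  stopifnot(inherits(F, "feature_matrix"))
  if (sd(snr) == 0) stop("constant SNR map")
  X <- valid_features(F)
  drop_j <- vapply(seq_len(ncol(X)), function(j) {
    sp <- spin_pvalue(snr, X[, j], spins,
                      stat = function(a, b) cor(a, b), tail = "two")
    sp$p < alpha
  }, TRUE)
  if (all(drop_j)) stop("all features associated with SNR; nothing retained")
  keep <- colnames(X)[!drop_j]
  newvals <- F$values[, keep, drop = FALSE]
  out <- feature_matrix(newvals, valid = F$valid[keep],
                        normalized = F$normalized)
  attr(out, "dropped") <- colnames(X)[drop_j]
  out
}

#' Regress signal-to-noise ratio out of the features
#'
#' Per-feature ordinary least squares on an intercept plus the SNR map;
#' the residuals (orthogonal to SNR) replace each valid feature column.
#'
#' @param F a `feature_matrix`.
#' @param snr numeric regional SNR map.
#' @return A `feature_matrix` of residuals (no longer normalized).
#' @export
snr_regress <- function(F, snr) {
  stopifnot(inherits(F, "feature_matrix"))
  if (sd(snr) == 0) stop("constant SNR map")
  X <- F$values
  D <- cbind(1, snr)
  for (j in which(F$valid)) {
    fit <- lm.fit(D, X[, j])
    X[, j] <- fit$residuals
  }
  feature_matrix(X, valid = F$valid, normalized = FALSE)
}

#' PCA stability under feature subsampling
#'
#' Repeatedly samples `k` features without replacement, re-runs PCA, and
#' records the leading component's variance explained and the absolute
#' correlation of its score map with the full-set leading component
#' (after sign alignment).
#'
#' @param F a `feature_matrix` or matrix.
#' @param k features per subsample (>= 2).
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return data.frame with `rep`, `var_explained_1`, `abs_r`.
#' @export
subsample_pca <- function(F, k = 100L, reps = 1000L, seed = 1L) {
  X <- as_feature_values(F)
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(X)) stop("k exceeds the number of features")
  full <- run_pca(X)
  with_seed(offspring_seed(seed, "subsample_pca"), {
    out <- data.frame(rep = seq_len(reps), var_explained_1 = NA_real_,
                      abs_r = NA_real_)
    for (i in seq_len(reps)) {
      j <- sample.int(ncol(X), k)
      sub <- run_pca(X[, j, drop = FALSE])
      out$var_explained_1[i] <- sub$var_explained[1]
      out$abs_r[i] <- abs(cor(sub$scores[, 1], full$scores[, 1]))
    }
    out
  })
}

#' Orthogonal Procrustes alignment of weight matrices
#'
#' Finds the orthogonal transform minimizing the Frobenius distance to
#' the reference weights and applies it to the other matrix; absorbs sign
#' flips and axis rotations of component solutions.
#'
#' @param W_ref reference weights (features x components).
#' @param W_other weights to align (same shape, same feature order).
#' @return list with `aligned`, `rotation` and `distance` (Frobenius).
#' @export
procrustes_align <- function(W_ref, W_other) {
  W_ref <- as.matrix(W_ref); W_other <- as.matrix(W_other)
  if (!all(dim(W_ref) == dim(W_other)))
    stop("weight matrices must have the same shape")
  sv <- svd(crossprod(W_other, W_ref))
  rot <- sv$u %*% t(sv$v)
  aligned <- W_other %*% rot
  list(aligned = aligned, rotation = rot,
       distance = sqrt(sum((W_ref - aligned)^2)))
}
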