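## Spatial-autocorrelation-preserving permutation machinery ("spins").

## Uniform random rotation matrix via normalized quaternion sampling.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate spatial spin permutations
#'
#' For each spin a uniform random 3-D rotation is drawn, applied to the
#' left-hemisphere parcel coordinates, and mirrored across the sagittal
#' plane for the right hemisphere. Each region then receives the value of
#' the nearest rotated same-hemisphere region by great-circle distance;
#' nearest-neighbour assignment may duplicate source regions (it is not a
#' bijection).
#'
#' @param geom a `parcel_geometry`.
#' @param n_spins number of permutations (>= 1).
#' @param seed integer seed.
#' @return A `spin_set`: list with `perms` (n_spins x regions matrix of
#'   source-region indices), `seed` and `geometry_hash`.
#' @export
generate_spins <- function(geom, n_spins, seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"))
  if (n_spins < 1) stop("n_spins must be >= 1")
  xyz <- geometry_xyz(geom)
  iL <- which(geom$hemisphere == "L")
  iR <- which(geom$hemisphere == "R")
  M <- diag(c(-1, 1, 1))               # sagittal mirror
  with_seed(offspring_seed(seed, "spins"), {
    perms <- matrix(0L, n_spins, nrow(geom))
    for (s in seq_len(n_spins)) {
      Rot <- random_rotation()
      RotR <- M %*% Rot %*% M          # the same rotation, mirrored
      for (h in list(list(idx = iL, rot = Rot), list(idx = iR, rot = RotR))) {
        if (!length(h$idx)) next
        rotated <- xyz[h$idx, , drop = FALSE] %*% t(h$rot)
        cosang <- xyz[h$idx, , drop = FALSE] %*% t(rotated)
        perms[s, h$idx] <- h$idx[max.col(cosang, ties.method = "first")]
      }
    }
    structure(list(perms = perms, seed = seed,
                   geometry_hash = sprintf("R%d_%.6f", nrow(geom),
                                           sum(abs(xyz)))),
              class = "spin_set")
  })
}

#' @export
print.spin_set <- function(x, ...) {
  cat(sprintf("Spin set: %d permutations of %d regions (seed %d)\n",
              nrow(x$perms), ncol(x$perms), x$seed))
  invisible(x)
}

## Vectorized spin null distribution for Spearman correlation. Spin
## permutations duplicate source regions, so each permuted vector is
## re-ranked (ties averaged); the mean rank is always (n + 1) / 2.
spin_null_spearman <- function(x, y, perms) {
  n <- length(x)
  ryc <- rank(y) - (n + 1) / 2
  Rm <- t(apply(perms, 1, function(p) rank(x[p])))
  Rc <- Rm - (n + 1) / 2
  drop(Rc %*% ryc) / (sqrt(rowSums(Rc^2)) * sqrt(sum(ryc^2)))
}

#' Spin permutation p-value for a map association
#'
#' Computes the observed association between two regional maps and a
#' permutation p-value against the spin null, using the add-one formula
#' `p = (1 + #{null >= observed}) / (n_spins + 1)` (two-tailed on absolute
#' values by default), which is never exactly zero.
#'
#' @param x,y numeric regional maps sharing the spin geometry.
#' @param spins a `spin_set`.
#' @param stat association function `f(x, y)`; default Spearman rank
#'   correlation.
#' @param tail "two" (on absolute values) or "right".
#' @return list with `observed`, `p` and the `null` vector.
#' @export
spin_pvalue <- function(x, y, spins, stat = NULL, tail = c("two", "right")) {
  tail <- match.arg(tail)
  stopifnot(inherits(spins, "spin_set"))
  if (length(x) != ncol(spins$perms) || length(y) != length(x))
    stop("maps must match the spin geometry")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant map: association statistic undefined")
  if (is.null(stat)) {
    observed <- cor(x, y, method = "spearman")
    null <- spin_null_spearman(x, y, spins$perms)
  } else {
    observed <- stat(x, y)
    null <- vapply(seq_len(nrow(spins$perms)), function(i)
      stat(x[spins$perms[i, ]], y), 0)
  }
  p <- if (tail == "two")
    (1 + sum(abs(null) >= abs(observed))) / (nrow(spins$perms) + 1)
  else
    (1 + sum(null >= observed)) / (nrow(spins$perms) + 1)
  list(observed = observed, p = p, null = null)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control at level `q`; adjusted p-values are monotone in
#' rank.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `rejected` (logical) and `p_adjusted`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- p.adjust(pvals, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}
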