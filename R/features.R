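## Time-series feature primitives. Each primitive works on a single
## univariate series (plus the sampling rate where needed); the curated
## catalogue in catalogue.R composes them into a regions x features matrix.

#' Autocorrelation function (biased estimator)
#'
#' Computes `acf[l] = sum_t (x_t - xbar)(x_{t+l} - xbar) / sum_t (x_t - xbar)^2`
#' for lags 0..`max_lag`. The biased (divide-by-n) estimator is used for
#' positive-semidefiniteness and stability at long lags.
#'
#' @param x numeric series with non-zero variance.
#' @param max_lag maximum lag (< length(x) - 1).
#' @return numeric vector of length `max_lag + 1`; element 1 is lag 0 (= 1).
#' @export
compute_acf <- function(x, max_lag) {
  if (!all(is.finite(x))) stop("series must be finite")
  if (length(x) <= max_lag + 1) stop("series too short for requested max_lag")
  if (var(x) == 0) stop("constant series: autocorrelation undefined")
  drop(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

#' First zero-crossing time of the autocorrelation function
#'
#' Finds the first lag at which the ACF reaches zero or below, linearly
#' interpolated between the bracketing lags, and converts it to seconds.
#' If the ACF stays positive over the whole window the saturation value
#' `max_lag / fs` is returned with `saturated = TRUE`.
#'
#' @param acf_vals ACF values starting at lag 0 (must equal 1).
#' @param fs sampling rate in Hz.
#' @return list with `t_c` (seconds) and `saturated` (logical).
#' @export
acf_first_zero <- function(acf_vals, fs) {
  if (abs(acf_vals[1] - 1) > 1e-8) stop("acf_vals must start at lag 0 (= 1)")
  below <- which(acf_vals <= 0)
  if (!length(below))
    return(list(t_c = (length(acf_vals) - 1) / fs, saturated = TRUE))
  l <- below[1] - 1L                    # lag index of first non-positive value
  a_prev <- acf_vals[l]                 # value at lag l - 1
  a_curr <- acf_vals[l + 1L]
  frac <- if (a_prev == a_curr) 0 else a_prev / (a_prev - a_curr)
  list(t_c = (l - 1 + frac) / fs, saturated = FALSE)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the centered series into a profile, splits the profile into
#' non-overlapping windows at each scale, removes a polynomial trend of
#' the given order per window, and pools the RMS residual into the
#' fluctuation function F(s). The scaling exponent alpha is the slope of
#' the least-squares line of log F versus log s; white noise gives
#' alpha ~ 0.5 and 1/f (pink) noise alpha ~ 1.
#'
#' @param x numeric series.
#' @param scales integer window sizes; default 12 log-spaced scales from
#'   16 to length(x)/4.
#' @param order polynomial detrending order (default 1).
#' @return list with `alpha`, `fit_r2`, `scales`, `fluctuation`.
#' @export
dfa_alpha <- function(x, scales = NULL, order = 1L) {
  n <- length(x)
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(16), log(n / 4), length.out = 12))))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 2) stop("need at least two scales")
  if (min(scales) < order + 2) stop("min scale must be >= order + 2")
  if (max(scales) > n / 4) stop("max scale must be <= length(x)/4")
  if (n < 4 * min(scales)) stop("series too short for DFA")
  prof <- cumsum(x - mean(x))
  Fv <- vapply(scales, function(s) {
    nw <- n %/% s
    X <- matrix(prof[seq_len(nw * s)], nrow = s)
    B <- outer(seq_len(s), 0:order, `^`)
    Q <- qr.Q(qr(B))
    resid <- X - Q %*% crossprod(Q, X)
    sqrt(mean(resid^2))
  }, 0)
  if (any(Fv <= 1e-10 * max(sqrt(mean(prof^2)), 1e-300)))
    stop("degenerate fluctuation (trend fully removed at some scale)")
  fit <- lm.fit(cbind(1, log(scales)), log(Fv))
  alpha <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((log(Fv) - mean(log(Fv)))^2)
  list(alpha = unname(alpha), fit_r2 = r2, scales = scales,
       fluctuation = Fv)
}

#' Lag-1 autocorrelation after rolling linear detrending
#'
#' Fits and subtracts a straight line in each non-overlapping window of
#' `window` samples and returns the lag-1 autocorrelation of the
#' concatenated residuals. Captures how much serial structure survives
#' the removal of low-order local trends.
#'
#' @param x numeric series with non-zero variance.
#' @param window window length in samples (>= 3).
#' @return scalar residual lag-1 autocorrelation.
#' @export
rolling_detrend_acf1 <- function(x, window = 5L) {
  if (window < 3) stop("window must be >= 3")
  if (var(x) == 0) stop("constant series")
  n <- length(x)
  nw <- n %/% window
  X <- matrix(x[seq_len(nw * window)], nrow = window)
  B <- cbind(1, seq_len(window))
  Q <- qr.Q(qr(B))
  resid <- as.vector(X - Q %*% crossprod(Q, X))
  if (var(resid) < 1e-300) stop("degenerate residuals after detrending")
  compute_acf(resid, 1L)[2]
}

#' Multiscale coarse-grained variance ratios
#'
#' For each scale s, averages the series over non-overlapping blocks of s
#' samples and reports the block-mean variance relative to the raw
#' variance. For i.i.d. noise the ratio decays as 1/s; for smooth signals
#' it stays near 1.
#'
#' @param x numeric series.
#' @param scales integer block sizes (default 2, 4, ..., 64).
#' @return named numeric vector of ratios `var_s / var_1`.
#' @export
multiscale_variance <- function(x, scales = 2^(1:6)) {
  n <- length(x)
  if (n < 4 * max(scales)) stop("series too short for largest scale")
  v1 <- var(x)
  out <- vapply(scales, function(s) {
    if (s == 1) return(1)
    nb <- n %/% s
    bm <- colMeans(matrix(x[seq_len(nb * s)], nrow = s))
    var(bm) / v1
  }, 0)
  names(out) <- paste0("scale_", scales)
  out
}

#' Sample entropy
#'
#' Standard sample entropy `-ln(A/B)` with Chebyshev distance and
#' self-matches excluded, where B counts matching templates of length `m`
#' and A those of length `m + 1` within tolerance `r`.
#'
#' @param x numeric series (length >= 100).
#' @param m embedding dimension (default 2).
#' @param r tolerance; default 0.2 times the series SD.
#' @return scalar entropy; `Inf` if no (m+1)-templates match (flagged
#'   ceiling value).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  if (length(x) < 100) stop("series too short for sample entropy")
  if (!all(is.finite(x))) stop("series must be finite")
  if (sd(x) == 0) stop("constant series: sample entropy undefined")
  counts <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  B <- counts[1]; A <- counts[2]
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}
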