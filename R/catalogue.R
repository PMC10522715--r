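## Curated feature catalogue. A fixed, documented set of ~55 named
## features spanning distribution, autocorrelation, fluctuation, spectral,
## model-fit, multiscale and entropy families. The pipeline treats the
## catalogue as pluggable; each entry is computable from one univariate
## series plus the sampling rate. Expensive intermediates (ACF, Welch PSD)
## are cached per series in a context environment shared by the entries.

ctx_acf <- function(ctx, x, max_lag) {
  max_lag <- min(max_lag, length(x) - 2L)
  if (is.null(ctx$acf) || length(ctx$acf) < max_lag + 1)
    ctx$acf <- compute_acf(x, max_lag)
  ctx$acf
}

ctx_psd <- function(ctx, x, fs) {
  if (is.null(ctx$psd))
    ctx$psd <- welch_one(x, fs, window_s = min(4, length(x) / fs / 2),
                         overlap = 0.5)
  ctx$psd
}

ACF_MAXLAG <- 1000L

## order-2 Yule-Walker solve from ACF values (lag 0, 1, 2, ...)
yw_ar2 <- function(a) solve(rbind(c(1, a[2]), c(a[2], 1)), a[2:3])

catalogue_entry <- function(name, family, fn) {
  list(name = name, family = family, fn = fn)
}

#' The default time-series feature catalogue
#'
#' Returns the curated catalogue of named features: moments and quantile
#' spread of the amplitude distribution; autocorrelations at lags 2, 4,
#' ..., 40 samples; the first zero-crossing time of the ACF; detrended
#' fluctuation analysis exponents (orders 1 and 2) with their fit R2;
#' lag-1 autocorrelation of rolling-window detrended residuals; six
#' canonical band powers, their relative versions, spectral entropy and
#' spectral centroid; AR(1)/AR(2) coefficients and residual variance;
#' multiscale block-mean variance ratios; and sample entropy (computed on
#' the first 5000 samples for tractability).
#'
#' @return A `feature_catalogue`: list of entries with `name`, `family`
#'   and the computing function `fn(x, fs, ctx)`.
#' @export
feature_catalogue <- function() {
  entries <- list(
    catalogue_entry("dist_mean", "distribution",
                    function(x, fs, ctx) mean(x)),
    catalogue_entry("dist_sd", "distribution",
                    function(x, fs, ctx) sd(x)),
    catalogue_entry("dist_skewness", "distribution",
                    function(x, fs, ctx) e1071::skewness(x, type = 1)),
    catalogue_entry("dist_kurtosis", "distribution",
                    function(x, fs, ctx) e1071::kurtosis(x, type = 1)),
    catalogue_entry("dist_iqr", "distribution",
                    function(x, fs, ctx) unname(diff(quantile(x, c(0.25, 0.75)))))
  )
  for (lag in seq(2, 40, by = 2)) {
    local({
      l <- lag
      entries[[length(entries) + 1L]] <<- catalogue_entry(
        sprintf("acf_lag_%02d", l), "autocorrelation",
        function(x, fs, ctx) ctx_acf(ctx, x, ACF_MAXLAG)[l + 1])
    })
  }
  entries <- c(entries, list(
    catalogue_entry("acf_first_zero_s", "autocorrelation",
                    function(x, fs, ctx)
                      acf_first_zero(ctx_acf(ctx, x, ACF_MAXLAG), fs)$t_c),
    catalogue_entry("rolling_detrend_acf1", "autocorrelation",
                    function(x, fs, ctx) rolling_detrend_acf1(x, 5L)),
    catalogue_entry("dfa_alpha_o1", "fluctuation",
                    function(x, fs, ctx) {
                      if (is.null(ctx$dfa1)) ctx$dfa1 <- dfa_alpha(x, order = 1L)
                      ctx$dfa1$alpha
                    }),
    catalogue_entry("dfa_r2_o1", "fluctuation",
                    function(x, fs, ctx) {
                      if (is.null(ctx$dfa1)) ctx$dfa1 <- dfa_alpha(x, order = 1L)
                      ctx$dfa1$fit_r2
                    }),
    catalogue_entry("dfa_alpha_o2", "fluctuation",
                    function(x, fs, ctx) {
                      if (is.null(ctx$dfa2)) ctx$dfa2 <- dfa_alpha(x, order = 2L)
                      ctx$dfa2$alpha
                    }),
    catalogue_entry("dfa_r2_o2", "fluctuation",
                    function(x, fs, ctx) {
                      if (is.null(ctx$dfa2)) ctx$dfa2 <- dfa_alpha(x, order = 2L)
                      ctx$dfa2$fit_r2
                    })
  ))
  for (band in names(canonical_bands())) {
    local({
      b <- band
      entries[[length(entries) + 1L]] <<- catalogue_entry(
        sprintf("bp_%s", b), "spectral",
        function(x, fs, ctx) {
          psd <- ctx_psd(ctx, x, fs)
          lim <- canonical_bands()[[b]]
          idx <- psd$freqs >= lim[1] & psd$freqs <= lim[2]
          if (!any(idx)) stop("empty band")
          mean(psd$power[idx])
        })
      entries[[length(entries) + 1L]] <<- catalogue_entry(
        sprintf("relbp_%s", b), "spectral",
        function(x, fs, ctx) {
          psd <- ctx_psd(ctx, x, fs)
          lim <- canonical_bands()[[b]]
          idx <- psd$freqs >= lim[1] & psd$freqs <= lim[2]
          if (!any(idx)) stop("empty band")
          sum(psd$power[idx]) / sum(psd$power)
        })
    })
  }
  entries <- c(entries, list(
    catalogue_entry("spectral_entropy", "spectral",
                    function(x, fs, ctx) {
                      psd <- ctx_psd(ctx, x, fs)
                      p <- psd$power[-1]
                      p <- p / sum(p)
                      -sum(p * log(p)) / log(length(p))
                    }),
    catalogue_entry("spectral_centroid", "spectral",
                    function(x, fs, ctx) {
                      psd <- ctx_psd(ctx, x, fs)
                      sum(psd$freqs * psd$power) / sum(psd$power)
                    }),
    ## Yule-Walker AR coefficients in closed form from the biased ACF
    ## (consistent with the catalogue's ACF estimator); residual variance
    ## reported as the innovation-variance ratio 1 - phi' r
    catalogue_entry("ar1_coef", "model",
                    function(x, fs, ctx) ctx_acf(ctx, x, ACF_MAXLAG)[2]),
    catalogue_entry("ar2_coef1", "model",
                    function(x, fs, ctx) yw_ar2(ctx_acf(ctx, x, ACF_MAXLAG))[1]),
    catalogue_entry("ar2_coef2", "model",
                    function(x, fs, ctx) yw_ar2(ctx_acf(ctx, x, ACF_MAXLAG))[2]),
    catalogue_entry("ar2_resid_var", "model",
                    function(x, fs, ctx) {
                      a <- ctx_acf(ctx, x, ACF_MAXLAG)
                      phi <- yw_ar2(a)
                      1 - sum(phi * a[2:3])
                    })
  ))
  for (sc in 2^(1:6)) {
    local({
      s <- sc
      entries[[length(entries) + 1L]] <<- catalogue_entry(
        sprintf("msv_scale_%02d", s), "multiscale",
        function(x, fs, ctx) {
          if (is.null(ctx$msv)) ctx$msv <- multiscale_variance(x)
          ctx$msv[[paste0("scale_", s)]]
        })
    })
  }
  entries <- c(entries, list(
    catalogue_entry("sample_entropy", "entropy",
                    function(x, fs, ctx)
                      sample_entropy(x[seq_len(min(length(x), 5000L))]))
  ))
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(entries, class = "feature_catalogue")
}

#' @export
print.feature_catalogue <- function(x, ...) {
  fam <- table(vapply(x, `[[`, "", "family"))
  cat(sprintf("Feature catalogue: %d features (%s)\n", length(x),
              paste(sprintf("%s %d", names(fam), fam), collapse = ", ")))
  invisible(x)
}

#' Compute the regions x features matrix
#'
#' Extracts each catalogue feature from the configured segment of every
#' regional series (dropping the initial `segment_drop_s` seconds and
#' using the next `segment_use_s` seconds). A feature column is marked
#' invalid when it errors or produces a non-finite value for any region,
#' or is constant across regions; the whole column is then flagged and
#' excluded from downstream analysis.
#'
#' @param ts a `regional_ts`.
#' @param cat a `feature_catalogue`.
#' @param cfg an `analysis_config` (segment settings).
#' @return An unnormalized `feature_matrix`.
#' @export
compute_feature_matrix <- function(ts, cat = feature_catalogue(),
                                   cfg = analysis_config()) {
  stopifnot(inherits(ts, "regional_ts"), inherits(cat, "feature_catalogue"))
  drop_n <- round(cfg$segment_drop_s * ts$fs)
  use_n <- round(cfg$segment_use_s * ts$fs)
  if (drop_n + use_n > ncol(ts$values)) {
    stop(sprintf("series too short for region '%s': need %d samples (drop %g s + use %g s), have %d",
                 rownames(ts$values)[1], drop_n + use_n, cfg$segment_drop_s,
                 cfg$segment_use_s, ncol(ts$values)))
  }
  R <- nrow(ts$values)
  vals <- matrix(NA_real_, R, length(cat),
                 dimnames = list(rownames(ts$values),
                                 vapply(cat, `[[`, "", "name")))
  for (r in seq_len(R)) {
    x <- ts$values[r, (drop_n + 1):(drop_n + use_n)]
    ctx <- new.env(parent = emptyenv())
    for (e in cat) {
      vals[r, e$name] <- tryCatch(as.numeric(e$fn(x, ts$fs, ctx))[1],
                                  error = function(err) NA_real_)
    }
  }
  valid <- apply(vals, 2, function(v)
    all(is.finite(v)) && (R < 2 || var(v) > 0))
  feature_matrix(vals, valid = valid, normalized = FALSE)
}

#' Outlier-robust sigmoid normalization
#'
#' Applies `x_norm = 1 / (1 + exp(-(x - <x>) / IQR_x))` where `<x>` is the
#' slice median and `IQR_x` the normalized interquartile range
#' (IQR / 1.35, approximating the SD under normality), followed by a
#' min-max rescale of each slice to [0, 1]. Slices with zero IQR are
#' flagged invalid, never silently passed through.
#'
#' For `axis = "across_regions"` (feature matrices, regions x features)
#' and `axis = "across_genes"` (genes x samples, per-sample slices) the
#' statistics are computed per column; for `axis = "across_samples"`
#' (genes x samples, per-gene slices) per row.
#'
#' @param M numeric matrix or `feature_matrix`.
#' @param axis which margin forms a normalization slice.
#' @return Same shape as the input; for a `feature_matrix` input a
#'   normalized `feature_matrix` with zero-IQR columns flagged invalid,
#'   for a matrix input a matrix with attribute `invalid_slices`.
#' @export
sigmoid_normalize <- function(M, axis = c("across_regions", "across_genes",
                                          "across_samples")) {
  axis <- match.arg(axis)
  is_fm <- inherits(M, "feature_matrix")
  vals <- if (is_fm) M$values else as.matrix(M)
  byrow <- axis == "across_samples"
  if (byrow) vals <- t(vals)
  norm_col <- function(v) {
    if (!all(is.finite(v))) return(rep(NA_real_, length(v)))
    iqr <- unname(diff(quantile(v, c(0.25, 0.75)))) / 1.35
    if (iqr <= 0) return(rep(NA_real_, length(v)))
    s <- 1 / (1 + exp(-(v - median(v)) / iqr))
    (s - min(s)) / (max(s) - min(s))
  }
  out <- apply(vals, 2, norm_col)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(vals))
  dimnames(out) <- dimnames(vals)
  invalid <- apply(out, 2, function(v) any(!is.finite(v)))
  if (byrow) out <- t(out)
  if (is_fm) {
    feature_matrix(out, valid = M$valid & !invalid, normalized = TRUE)
  } else {
    attr(out, "invalid_slices") <- which(invalid)
    out
  }
}

#' Feature stability across segment lengths
#'
#' Computes the catalogue features on cumulative segments of increasing
#' length and reports, per consecutive length pair, the Pearson
#' correlation between the two feature vectors, averaged over regions.
#' Stable features produce correlations approaching 1 as segments grow.
#'
#' @param ts a `regional_ts` long enough for the largest length.
#' @param lengths_s increasing segment lengths in seconds.
#' @param cat a `feature_catalogue`.
#' @return data.frame with `length_s`, `prev_length_s` and mean Pearson
#'   `r` across regions for each consecutive pair.
#' @export
segment_stability <- function(ts, lengths_s = seq(5, 125, by = 5),
                              cat = feature_catalogue()) {
  stopifnot(inherits(ts, "regional_ts"))
  lengths_s <- sort(lengths_s)
  if (max(lengths_s) * ts$fs > ncol(ts$values))
    stop("series too short for the largest segment length")
  R <- nrow(ts$values)
  fmat <- lapply(lengths_s, function(L) {
    cfg_l <- analysis_config(segment_drop_s = 0, segment_use_s = L)
    compute_feature_matrix(ts, cat, cfg_l)$values
  })
  out <- data.frame(length_s = lengths_s[-1],
                    prev_length_s = lengths_s[-length(lengths_s)],
                    r = NA_real_)
  for (i in seq_len(length(lengths_s) - 1L)) {
    rs <- vapply(seq_len(R), function(reg) {
      a <- fmat[[i]][reg, ]; b <- fmat[[i + 1]][reg, ]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      cor(a[ok], b[ok])
    }, 0)
    out$r[i] <- mean(rs, na.rm = TRUE)
  }
  out
}
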