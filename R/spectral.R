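## Welch spectral estimation and knee-mode spectral parameterization.

## Welch PSD of a single series: Hann taper, mean-detrended overlapping
## segments, one-sided density scaling (integral over [0, fs/2] ~ variance).
welch_one <- function(x, fs, window_s = 4, overlap = 0.5) {
  n <- length(x)
  nw <- round(window_s * fs)
  if (nw > n) stop("Welch window longer than series")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nw - 1) / nw))
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  nf <- nw %/% 2
  acc <- numeric(nf + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- Mod(X[1:(nf + 1)])^2
    acc <- acc + p
  }
  p <- acc / length(starts) / (fs * sum(w^2))
  if (nf >= 2) p[2:nf] <- 2 * p[2:nf]   # one-sided: double all but DC/Nyquist
  list(freqs = (0:nf) * fs / nw, power = p)
}

#' Welch power spectral density
#'
#' Estimates a one-sided PSD per region using Hann-tapered overlapping
#' windows with segment averaging. Density scaling is such that the
#' integral of the PSD over [0, fs/2] approximates the signal variance.
#'
#' @param ts a `regional_ts`.
#' @param cfg an `analysis_config` (window length and overlap).
#' @return A `power_spectrum`: list with `freqs` (Hz) and `power`
#'   (regions x frequencies matrix, power per Hz).
#' @export
welch_psd <- function(ts, cfg = analysis_config()) {
  stopifnot(inherits(ts, "regional_ts"))
  first <- welch_one(ts$values[1, ], ts$fs, cfg$welch_window_s,
                     cfg$welch_overlap)
  power <- matrix(0, nrow(ts$values), length(first$freqs),
                  dimnames = list(rownames(ts$values), NULL))
  power[1, ] <- first$power
  if (nrow(ts$values) > 1)
    for (r in 2:nrow(ts$values))
      power[r, ] <- welch_one(ts$values[r, ], ts$fs, cfg$welch_window_s,
                              cfg$welch_overlap)$power
  structure(list(freqs = first$freqs, power = power),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d regions, %d frequencies (%.3g-%.4g Hz)\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Band-limited power maps
#'
#' Mean spectral density over the frequency bins falling inside each band
#' (inclusive edges), one regional map per band.
#'
#' @param psd a `power_spectrum`.
#' @param bands named list of length-2 numeric band edges in Hz; defaults
#'   to the six canonical bands.
#' @return A `brain_maps` object with one column per band.
#' @export
band_power <- function(psd, bands = canonical_bands()) {
  stopifnot(inherits(psd, "power_spectrum"))
  m <- vapply(names(bands), function(b) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    if (lo < min(psd$freqs) || hi > max(psd$freqs))
      stop(sprintf("band '%s' (%g-%g Hz) outside the frequency grid", b, lo, hi))
    idx <- which(psd$freqs >= lo & psd$freqs <= hi)
    if (!length(idx))
      stop(sprintf("band '%s' contains no frequency bins", b))
    rowMeans(psd$power[, idx, drop = FALSE])
  }, numeric(nrow(psd$power)))
  brain_maps(m, map_name = names(bands), region_id = rownames(psd$power))
}

#' Knee frequency of the aperiodic component
#'
#' The frequency where the aperiodic spectrum bends: `f_k = k^(1/chi)`.
#'
#' @param k knee parameter (>= 0).
#' @param chi aperiodic exponent (> 0).
#' @return knee frequency in Hz.
#' @export
knee_frequency <- function(k, chi) {
  stopifnot(all(k >= 0), all(chi > 0))
  k^(1 / chi)
}

#' Intrinsic timescale from the knee frequency
#'
#' `tau = 1 / (2 pi f_k)`: the characteristic autocorrelation decay time
#' implied by the bend of the aperiodic spectrum.
#'
#' @param f_k knee frequency in Hz (> 0).
#' @return timescale in seconds.
#' @export
intrinsic_timescale <- function(f_k) {
  stopifnot(all(f_k > 0))
  1 / (2 * pi * f_k)
}

## Aperiodic model in log10-power space.
ap_model <- function(f, offset, knee, chi) offset - log10(knee + f^chi)

gauss_peaks <- function(f, peaks) {
  g <- numeric(length(f))
  if (nrow(peaks))
    for (i in seq_len(nrow(peaks)))
      g <- g + peaks$amplitude[i] *
        exp(-(f - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  g
}

fit_aperiodic <- function(f, y, start) {
  res <- try(minpack.lm::nls.lm(
    par = start,
    lower = c(offset = -Inf, knee = 0, chi = 1e-3),
    upper = c(offset = Inf, knee = Inf, chi = 10),
    fn = function(p) y - ap_model(f, p[["offset"]], p[["knee"]], p[["chi"]]),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  as.list(res$par)
}

fit_one_gaussian <- function(f, resid, width_lim) {
  i <- which.max(resid)                 # ties: which.max takes lowest freq
  guess_c <- f[i]; guess_a <- resid[i]
  half <- guess_a / 2
  above <- resid >= half
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(f) && above[hi + 1]) hi <- hi + 1
  guess_w <- max(width_lim[1],
                 min(width_lim[2], (f[hi] - f[lo]) / 2.355))
  res <- try(minpack.lm::nls.lm(
    par = c(center = guess_c, amplitude = guess_a, width = guess_w),
    lower = c(center = max(min(f), guess_c - 2 * guess_w),
              amplitude = 0, width = width_lim[1]),
    upper = c(center = min(max(f), guess_c + 2 * guess_w),
              amplitude = Inf, width = width_lim[2]),
    fn = function(p) resid - p[["amplitude"]] *
      exp(-(f - p[["center"]])^2 / (2 * p[["width"]]^2)),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  as.list(res$par)
}

fit_spectrum_one <- function(f, y, cfg) {
  ## initialization: offset from the lowest fitted frequency, exponent from
  ## the endpoint slope, knee placed at 10 Hz
  chi0 <- max(0.1, min(8, -(y[length(y)] - y[1]) /
                         (log10(f[length(f)]) - log10(f[1]))))
  starts <- list(
    c(offset = y[1] + log10(10^chi0 + f[1]^chi0), knee = 10^chi0, chi = chi0),
    c(offset = y[1], knee = 1, chi = chi0),
    c(offset = y[1] + 2, knee = 100^chi0, chi = chi0))
  ap <- NULL
  for (s in starts) {
    ap <- fit_aperiodic(f, y, s)
    if (!is.null(ap)) break
  }
  if (is.null(ap)) return(NULL)
  ## robust refit: mask the most peak-contaminated (high-residual) bins
  resid <- y - ap_model(f, ap$offset, ap$knee, ap$chi)
  keep <- resid <= quantile(resid, 0.75)
  ap2 <- fit_aperiodic(f[keep], y[keep],
                       c(offset = ap$offset, knee = ap$knee, chi = ap$chi))
  if (!is.null(ap2)) ap <- ap2

  ## iterative residual peak extraction
  peaks <- data.frame(center = numeric(0), amplitude = numeric(0),
                      width = numeric(0))
  resid <- y - ap_model(f, ap$offset, ap$knee, ap$chi)
  for (it in seq_len(cfg$max_n_peaks)) {
    thr <- max(cfg$min_peak_height, cfg$peak_threshold * sd(resid))
    if (max(resid) < thr) break
    pk <- fit_one_gaussian(f, resid, cfg$peak_width_limits_hz)
    if (is.null(pk) || pk$amplitude < cfg$min_peak_height) break
    peaks <- rbind(peaks, as.data.frame(pk))
    resid <- resid - pk$amplitude *
      exp(-(f - pk$center)^2 / (2 * pk$width^2))
  }

  ## aperiodic refit on the peak-removed spectrum
  y_flat <- y - gauss_peaks(f, peaks)
  ap3 <- fit_aperiodic(f, y_flat,
                       c(offset = ap$offset, knee = ap$knee, chi = ap$chi))
  if (!is.null(ap3)) ap <- ap3

  ## joint polish of aperiodic + peak parameters
  if (nrow(peaks)) {
    p0 <- c(offset = ap$offset, knee = ap$knee, chi = ap$chi,
            as.vector(t(as.matrix(peaks))))
    np <- nrow(peaks)
    lower <- c(-Inf, 0, 1e-3,
               rep(c(min(f), 0, cfg$peak_width_limits_hz[1]), np))
    upper <- c(Inf, Inf, 10,
               rep(c(max(f), Inf, cfg$peak_width_limits_hz[2]), np))
    jointfn <- function(p) {
      pk <- data.frame(center = p[3 + 3 * (seq_len(np) - 1) + 1],
                       amplitude = p[3 + 3 * (seq_len(np) - 1) + 2],
                       width = p[3 + 3 * (seq_len(np) - 1) + 3])
      y - ap_model(f, p[1], p[2], p[3]) - gauss_peaks(f, pk)
    }
    res <- try(minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                                  fn = jointfn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300)), silent = TRUE)
    if (!inherits(res, "try-error")) {
      p <- res$par
      ap <- list(offset = p[1], knee = p[2], chi = p[3])
      peaks <- data.frame(center = p[3 + 3 * (seq_len(np) - 1) + 1],
                          amplitude = p[3 + 3 * (seq_len(np) - 1) + 2],
                          width = p[3 + 3 * (seq_len(np) - 1) + 3])
    }
  }
  model <- ap_model(f, ap$offset, ap$knee, ap$chi) + gauss_peaks(f, peaks)
  r2 <- suppressWarnings(cor(model, y))^2
  list(ap = ap, peaks = peaks, r2 = r2)
}

#' Fit the knee-mode spectral parameterization model
#'
#' Decomposes each region's PSD, in log10-power space over the configured
#' fit range, into an aperiodic component
#' `log10 P = offset - log10(knee + f^chi)` and up to `max_n_peaks`
#' Gaussian oscillatory peaks. The procedure is: robust aperiodic fit;
#' iterative residual peak detection (largest residual exceeding
#' `max(min_peak_height, peak_threshold * residual SD)` seeds a Gaussian,
#' fitted and subtracted, widths clipped to the configured limits);
#' aperiodic refit on the peak-removed spectrum; joint least-squares
#' polish. Goodness of fit is the squared Pearson correlation between
#' model and data in log space. The knee frequency `f_k = knee^(1/chi)`
#' and intrinsic timescale `tau = 1/(2 pi f_k)` are derived per region.
#'
#' @param psd a `power_spectrum`.
#' @param cfg an `analysis_config`; `fit_range_hz` (default 1-60 Hz), peak
#'   settings and width limits are taken from it.
#' @return A `spectral_fit` object: `aperiodic` data.frame (region_id,
#'   offset, knee, chi, r2, f_k, tau, n_peaks, converged) and `peaks`
#'   data.frame (region_id, center, amplitude, width). Non-converged
#'   regions carry NA parameters and `converged = FALSE`.
#' @export
fit_spectral_model <- function(psd, cfg = analysis_config()) {
  stopifnot(inherits(psd, "power_spectrum"))
  sel <- psd$freqs >= cfg$fit_range_hz[1] & psd$freqs <= cfg$fit_range_hz[2]
  if (sum(sel) < 10) stop("too few frequency bins in the fit range")
  f <- psd$freqs[sel]
  ids <- rownames(psd$power)
  n <- nrow(psd$power)
  ap_out <- data.frame(region_id = ids, offset = NA_real_, knee = NA_real_,
                       chi = NA_real_, r2 = NA_real_, f_k = NA_real_,
                       tau = NA_real_, n_peaks = 0L, converged = FALSE,
                       stringsAsFactors = FALSE)
  pk_out <- data.frame(region_id = character(0), center = numeric(0),
                       amplitude = numeric(0), width = numeric(0),
                       stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    p <- psd$power[r, sel]
    if (any(p <= 0)) next                # flagged non-converged
    fit <- fit_spectrum_one(f, log10(p), cfg)
    if (is.null(fit)) next
    ap_out$offset[r] <- fit$ap$offset
    ap_out$knee[r] <- fit$ap$knee
    ap_out$chi[r] <- fit$ap$chi
    ap_out$r2[r] <- fit$r2
    ap_out$f_k[r] <- knee_frequency(max(fit$ap$knee, 0), fit$ap$chi)
    ap_out$tau[r] <- if (ap_out$f_k[r] > 0)
      intrinsic_timescale(ap_out$f_k[r]) else NA_real_
    ap_out$n_peaks[r] <- nrow(fit$peaks)
    ap_out$converged[r] <- TRUE
    if (nrow(fit$peaks))
      pk_out <- rbind(pk_out, data.frame(region_id = ids[r], fit$peaks,
                                         stringsAsFactors = FALSE))
  }
  if (!any(ap_out$converged))
    warning("no region produced a converged spectral fit")
  structure(list(aperiodic = ap_out, peaks = pk_out,
                 fit_range_hz = cfg$fit_range_hz),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  ok <- x$aperiodic$converged
  cat(sprintf("Spectral fit (knee mode, %g-%g Hz): %d/%d regions converged\n",
              x$fit_range_hz[1], x$fit_range_hz[2], sum(ok), length(ok)))
  if (any(ok))
    cat(sprintf("  median chi %.2f, median knee freq %.2f Hz, median tau %.4g s, median R2 %.3f\n",
                median(x$aperiodic$chi[ok]), median(x$aperiodic$f_k[ok]),
                median(x$aperiodic$tau[ok]), median(x$aperiodic$r2[ok])))
  invisible(x)
}

#' @export
summary.spectral_fit <- function(object, ...) {
  print(object)
  ok <- object$aperiodic$converged
  if (any(ok)) {
    cat("Aperiodic parameter quartiles (converged regions):\n")
    print(apply(object$aperiodic[ok, c("offset", "knee", "chi", "f_k",
                                       "tau", "r2")], 2, quantile,
                probs = c(0.25, 0.5, 0.75)))
  }
  invisible(object)
}

#' @export
coef.spectral_fit <- function(object, ...) {
  object$aperiodic[, c("region_id", "offset", "knee", "chi", "f_k", "tau")]
}

#' Band-limited oscillation scores
#'
#' For each band and region: take, per subject, the in-band fitted peak
#' with maximum amplitude (if any); average peak amplitude across the
#' subjects that show a peak; normalize by the maximum across regions;
#' multiply by the probability map, i.e. the fraction of subjects with at
#' least one in-band peak at that region.
#'
#' @param fits list of `spectral_fit` objects, one per subject, sharing
#'   region order.
#' @param bands named list of band intervals; default the oscillation-score
#'   bands (delta 2-4, theta 5-7, alpha 8-14, beta 15-30 Hz).
#' @return A `brain_maps` with one score map per band, values in [0, 1].
#' @export
oscillation_score <- function(fits, bands = oscillation_bands()) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "spectral_fit")))
  ids <- fits[[1]]$aperiodic$region_id
  ns <- length(fits)
  out <- matrix(0, length(ids), length(bands),
                dimnames = list(ids, names(bands)))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    amp <- matrix(NA_real_, length(ids), ns)
    for (s in seq_len(ns)) {
      pk <- fits[[s]]$peaks
      pk <- pk[pk$center >= lo & pk$center <= hi, , drop = FALSE]
      if (nrow(pk)) {
        for (i in seq_along(ids)) {
          pr <- pk[pk$region_id == ids[i], , drop = FALSE]
          if (nrow(pr)) amp[i, s] <- max(pr$amplitude)
        }
      }
    }
    prob <- rowMeans(!is.na(amp))
    mean_amp <- rowMeans(amp, na.rm = TRUE)
    mean_amp[is.nan(mean_amp)] <- 0
    if (all(mean_amp == 0)) {
      warning(sprintf("no in-band peaks detected for band '%s'", b))
      next
    }
    out[, b] <- mean_amp / max(mean_amp) * prob
  }
  brain_maps(out, map_name = names(bands), region_id = ids)
}

#' Source-level signal-to-noise ratio
#'
#' `SNR = 10 log10( (a^2 / N) sum_k b_k^2 / s_k^2 )` in dB per region,
#' where `a` is the source amplitude, `b_k` the per-sensor gain of a unit
#' source and `s_k^2` the sensor noise variance.
#'
#' @param fm a `forward_model`.
#' @return named numeric vector of SNR values in dB, one per region.
#' @export
compute_snr <- function(fm) {
  stopifnot(inherits(fm, "forward_model"))
  if (any(fm$noise_var <= 0)) stop("noise variances must be positive")
  N <- nrow(fm$gains)
  snr <- 10 * log10(fm$a^2 / N * colSums(fm$gains^2 / fm$noise_var))
  names(snr) <- fm$region_id
  snr
}
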