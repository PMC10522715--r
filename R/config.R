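#' Analysis configuration
#'
#' Bundles the tunable settings used across the pipeline: the random seed,
#' permutation and bootstrap counts, canonical frequency bands, Welch window
#' settings, the aperiodic fit range, and the segment used for feature
#' extraction (drop the initial transient, use a fixed-length segment).
#' Defaults follow standard MEG practice: six canonical bands, 4 s Hann
#' windows with 50% overlap, a 1-60 Hz aperiodic fit range, and an 80 s
#' feature-extraction segment after dropping the first 30 s.
#'
#' @param seed integer master seed.
#' @param n_spins number of spatial spin permutations.
#' @param n_boot number of bootstrap resamples.
#' @param bands named list of length-2 numeric vectors, band edges in Hz.
#' @param welch_window_s Welch window length in seconds.
#' @param welch_overlap fractional window overlap in [0, 1).
#' @param fit_range_hz length-2 numeric, frequency range for aperiodic fits.
#' @param segment_drop_s seconds discarded from the start of each series.
#' @param segment_use_s seconds of signal used after the dropped segment.
#' @param peak_width_limits_hz length-2 numeric, Gaussian peak width bounds.
#' @param max_n_peaks maximum number of spectral peaks fitted.
#' @param min_peak_height minimum peak height in log10-power units.
#' @param peak_threshold peak detection threshold in residual SD units.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(seed = 1L,
                            n_spins = 1000L,
                            n_boot = 1000L,
                            bands = canonical_bands(),
                            welch_window_s = 4,
                            welch_overlap = 0.5,
                            fit_range_hz = c(1, 60),
                            segment_drop_s = 30,
                            segment_use_s = 80,
                            peak_width_limits_hz = c(1, 6),
                            max_n_peaks = 6L,
                            min_peak_height = 0.1,
                            peak_threshold = 2) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_spins >= 1, n_boot >= 1,
            welch_window_s > 0,
            welch_overlap >= 0, welch_overlap < 1,
            length(fit_range_hz) == 2L, fit_range_hz[1] < fit_range_hz[2],
            segment_drop_s >= 0, segment_use_s > 0,
            length(peak_width_limits_hz) == 2L,
            peak_width_limits_hz[1] > 0,
            peak_width_limits_hz[1] <= peak_width_limits_hz[2],
            max_n_peaks >= 0, min_peak_height >= 0, peak_threshold >= 0)
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("`bands` must be a named list of frequency intervals")
  for (b in bands)
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2])
      stop("each band must be a numeric interval c(lo, hi) with lo < hi")
  structure(list(
    seed = as.integer(seed), n_spins = as.integer(n_spins),
    n_boot = as.integer(n_boot), bands = bands,
    welch_window_s = welch_window_s, welch_overlap = welch_overlap,
    fit_range_hz = fit_range_hz,
    segment_drop_s = segment_drop_s, segment_use_s = segment_use_s,
    peak_width_limits_hz = peak_width_limits_hz,
    max_n_peaks = as.integer(max_n_peaks),
    min_peak_height = min_peak_height, peak_threshold = peak_threshold
  ), class = "analysis_config")
}

#' Canonical electrophysiological frequency bands
#'
#' The six canonical bands used for band-limited power maps:
#' delta 2-4, theta 5-7, alpha 8-12, beta 15-29, lo-gamma 30-59 and
#' hi-gamma 60-90 Hz.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
canonical_bands <- function() {
  list(delta = c(2, 4), theta = c(5, 7), alpha = c(8, 12),
       beta = c(15, 29), lo_gamma = c(30, 59), hi_gamma = c(60, 90))
}

#' Oscillation-score frequency bands
#'
#' Band limits used for parameterized peak scoring, reflecting the
#' distribution of detected peak center frequencies: delta 2-4, theta 5-7,
#' alpha 8-14 and beta 15-30 Hz. Gamma bands are excluded because peak
#' detection is unreliable at high frequencies.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
oscillation_bands <- function() {
  list(delta = c(2, 4), theta = c(5, 7), alpha = c(8, 14), beta = c(15, 30))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  seed:", x$seed, " spins:", x$n_spins, " bootstraps:", x$n_boot, "\n")
  cat("  Welch:", x$welch_window_s, "s windows,",
      sprintf("%.0f%%", 100 * x$welch_overlap), "overlap\n")
  cat("  aperiodic fit range:", x$fit_range_hz[1], "-", x$fit_range_hz[2],
      "Hz; segment:", x$segment_use_s, "s after dropping",
      x$segment_drop_s, "s\n")
  cat("  bands:", paste(sprintf("%s %g-%g", names(x$bands),
                                vapply(x$bands, `[`, 0, 1),
                                vapply(x$bands, `[`, 0, 2)),
                        collapse = ", "), "\n")
  invisible(x)
}
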