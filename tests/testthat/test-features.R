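test_that("ACF matches closed forms and the brute-force oracle", {
  # sinusoid: acf(T/4) ~ 0, acf(T/2) ~ -1
  T0 <- 100
  x <- sin(2 * pi * (1:(50 * T0)) / T0)
  a <- compute_acf(x, T0)
  expect_lt(abs(a[T0 / 4 + 1]), 0.02)
  expect_lt(abs(a[T0 / 2 + 1] + 1), 0.02)

  # white noise lag-1 inside the asymptotic null band
  set.seed(1)
  w <- rnorm(10000)
  expect_lt(abs(compute_acf(w, 5)[2]), 3 / sqrt(10000))

  # AR(1) phi = 0.9: acf[k] ~ 0.9^k
  set.seed(2)
  ar1 <- as.numeric(arima.sim(list(ar = 0.9), 200000))
  a <- compute_acf(ar1, 10)
  expect_true(all(abs(a[2:11] - 0.9^(1:10)) < 0.02))

  # brute-force agreement
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(300)
    expect_equal(compute_acf(x, 20), oracle_acf(x, 20), tolerance = 1e-10)
  }
  expect_error(compute_acf(rep(1, 100), 10), "constant")
})

test_that("ACF first zero-crossing interpolates and saturates correctly", {
  T0 <- 100; fs <- 100
  x <- sin(2 * pi * (1:(50 * T0)) / T0)
  fz <- acf_first_zero(compute_acf(x, 2 * T0), fs)
  expect_false(fz$saturated)
  expect_lt(abs(fz$t_c - T0 / 4 / fs), 1 / fs)

  # strictly positive acf: saturation flag
  fz2 <- acf_first_zero(c(1, 0.9, 0.8, 0.7), fs)
  expect_true(fz2$saturated)
  expect_equal(fz2$t_c, 3 / fs)

  # white noise crosses early: the first non-positive sample ACF falls at
  # lag 1 or 2 whenever r1 <= 0 or r2 <= 0, i.e. with asymptotic
  # probability 1 - P(r1 > 0, r2 > 0) = 3/4 (r1, r2 independent N(0, 1/n))
  set.seed(4)
  hits <- vapply(1:200, function(i) {
    a <- compute_acf(rnorm(2000), 50)
    acf_first_zero(a, fs)$t_c <= 2 / fs
  }, TRUE)
  expect_gt(mean(hits), 0.65)
  expect_lt(mean(hits), 0.85)
})

test_that("DFA recovers known scaling exponents and matches the oracle", {
  set.seed(5)
  aw <- replicate(20, dfa_alpha(rnorm(20000))$alpha)
  expect_gte(mean(aw > 0.45 & aw < 0.55), 0.9)
  ap <- replicate(20, dfa_alpha(colored_noise(20000, 1))$alpha)
  expect_gte(mean(ap > 0.9 & ap < 1.1), 0.9)

  x <- rnorm(4000)
  scales <- c(16, 32, 64, 128, 256)
  mine <- dfa_alpha(x, scales = scales, order = 1)
  ora <- oracle_dfa(x, scales, 1)
  expect_equal(mine$alpha, ora$alpha, tolerance = 1e-8)
  expect_equal(mine$fluctuation, ora$F, tolerance = 1e-8)

  mine2 <- dfa_alpha(x, scales = scales, order = 2)
  ora2 <- oracle_dfa(x, scales, 2)
  expect_equal(mine2$alpha, ora2$alpha, tolerance = 1e-8)

  # fully detrendable profiles are degenerate: a constant series has a
  # null profile; a linear ramp has a quadratic profile killed by order 2
  expect_error(dfa_alpha(rep(3, 2000), order = 1), "degenerate")
  expect_error(dfa_alpha(seq_len(2000) * 0.01, order = 2), "degenerate")
  expect_error(dfa_alpha(rnorm(30)), "short|scale")
})

test_that("rolling-window detrended lag-1 autocorrelation behaves", {
  set.seed(6)
  x <- rnorm(10000)
  expect_equal(rolling_detrend_acf1(x, 5),
               oracle_rolling_detrend_acf1(x, 5), tolerance = 1e-8)
  # white noise: detrending induces negative correlation, bounded
  v <- replicate(20, rolling_detrend_acf1(rnorm(10000), 5))
  expect_true(all(v < 0 & v > -0.8))
  # slow sinusoid + noise: residual acf1 near the pure-noise level
  t <- 1:20000
  slow <- sin(2 * pi * t / 5000) + rnorm(20000, sd = 0.5)
  pure <- rnorm(20000, sd = 0.5)
  expect_lt(abs(rolling_detrend_acf1(slow, 5) -
                rolling_detrend_acf1(pure, 5)), 0.05)
  # single window limit = acf1 of globally detrended series
  y <- cumsum(rnorm(500))
  expect_equal(rolling_detrend_acf1(y, 500),
               compute_acf(residuals(lm(y ~ seq_along(y))), 1)[2],
               tolerance = 1e-8)
  expect_error(rolling_detrend_acf1(rep(2, 100), 5), "constant")
})

test_that("multiscale variance follows the i.i.d. law and smooth-signal limit", {
  set.seed(7)
  x <- rnorm(60000)
  v <- multiscale_variance(x)
  expected <- 1 / 2^(1:6)
  expect_true(all(abs(v - expected) / expected < 0.2))
  # slow signal: ratios ~ 1
  slow <- 5 + sin(2 * pi * (1:4000) / 2000)
  vs <- multiscale_variance(slow, scales = c(2, 4, 8, 16, 32, 64))
  expect_true(all(vs > 0.95))
  expect_equal(unname(multiscale_variance(x, scales = 1)[1]), 1)
})

test_that("sample entropy matches the brute-force oracle and separates regimes", {
  set.seed(8)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
               tolerance = 1e-10)
  # periodic square wave: low entropy (oracle on n = 1000)
  sq <- rep(c(rep(1, 10), rep(-1, 10)), 50)
  se_sq <- sample_entropy(sq, 2, 0.2 * sd(sq))
  expect_equal(se_sq, oracle_sampen(sq, 2, 0.2 * sd(sq)), tolerance = 1e-10)
  expect_lt(se_sq, 0.25)     # transition mismatches alone: ~0.22 by oracle
  # white noise: high entropy
  expect_gt(sample_entropy(rnorm(5000)), 1.5)
  # determinism
  y <- rnorm(200)
  expect_identical(sample_entropy(y), sample_entropy(y))
})

test_that("every catalogue feature agrees with a brute-force reference", {
  cat_ <- feature_catalogue()
  fs <- 250                  # Nyquist above the highest canonical band
  set.seed(9)
  for (i in 1:20) {
    x <- as.numeric(arima.sim(list(ar = c(0.5, 0.2)), 1200)) + rnorm(1200, sd = 0.1)
    ctx <- new.env(parent = emptyenv())
    vals <- vapply(cat_, function(e) e$fn(x, fs, ctx), 0)
    a <- oracle_acf(x, 42)
    w <- oracle_welch(x, fs, window_s = min(4, length(x) / fs / 2),
                      overlap = 0.5)
    n <- length(x)
    ref <- c(
      dist_mean = sum(x) / n,
      dist_sd = sqrt(sum((x - mean(x))^2) / (n - 1)),
      dist_skewness = (sum((x - mean(x))^3) / n) /
        (sum((x - mean(x))^2) / n)^1.5,
      dist_kurtosis = (sum((x - mean(x))^4) / n) /
        (sum((x - mean(x))^2) / n)^2 - 3,
      dist_iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
      setNames(a[seq(2, 40, 2) + 1], sprintf("acf_lag_%02d", seq(2, 40, 2))),
      acf_first_zero_s = acf_first_zero(oracle_acf(x, 200), fs)$t_c,
      rolling_detrend_acf1 = oracle_rolling_detrend_acf1(x, 5),
      spectral_entropy = local({
        p <- w$power[-1] / sum(w$power[-1]); -sum(p * log(p)) / log(length(p))
      }),
      spectral_centroid = sum(w$freqs * w$power) / sum(w$power),
      ar1_coef = oracle_ar(x, 1)$ar,
      ar2_coef1 = oracle_ar(x, 2)$ar[1],
      ar2_coef2 = oracle_ar(x, 2)$ar[2],
      ar2_resid_var = oracle_ar(x, 2)$var_ratio,
      sample_entropy = oracle_sampen(x[1:min(n, 5000)], 2,
                                     0.2 * sd(x[1:min(n, 5000)]))
    )
    for (b in names(canonical_bands())) {
      lim <- canonical_bands()[[b]]
      idx <- w$freqs >= lim[1] & w$freqs <= lim[2]
      if (!any(idx)) next
      ref[[paste0("bp_", b)]] <- mean(w$power[idx])
      ref[[paste0("relbp_", b)]] <- sum(w$power[idx]) / sum(w$power)
    }
    for (s in 2^(1:6)) {
      nb <- n %/% s
      bm <- vapply(seq_len(nb), function(k) mean(x[((k - 1) * s + 1):(k * s)]), 0)
      ref[[sprintf("msv_scale_%02d", s)]] <- var(bm) / var(x)
    }
    dfa_scales <- unique(round(exp(seq(log(16), log(n / 4),
                                       length.out = 12))))
    ora_dfa1 <- oracle_dfa(x, dfa_scales, 1)
    ora_dfa2 <- oracle_dfa(x, dfa_scales, 2)
    ref[["dfa_alpha_o1"]] <- ora_dfa1$alpha
    ref[["dfa_alpha_o2"]] <- ora_dfa2$alpha
    ref[["dfa_r2_o1"]] <- summary(lm(log(ora_dfa1$F) ~ log(dfa_scales)))$r.squared
    ref[["dfa_r2_o2"]] <- summary(lm(log(ora_dfa2$F) ~ log(dfa_scales)))$r.squared
    for (nm in names(ref))
      expect_equal(vals[[nm]], ref[[nm]], tolerance = 1e-8,
                   label = sprintf("feature %s (series %d)", nm, i))
  }
})

test_that("feature matrix is deterministic and applies the removal rule", {
  geom <- generate_parcellation(4, seed = 10)
  tr <- planted_truth(geom, n_maps = 1, seed = 10)
  ts <- generate_timeseries(geom, tr, duration_s = 40, fs = 128, seed = 10)
  cfg <- analysis_config(segment_drop_s = 5, segment_use_s = 30)
  # identical series -> identical rows
  ts$values[2, ] <- ts$values[1, ]
  fm <- compute_feature_matrix(ts, feature_catalogue(), cfg)
  expect_equal(fm$values[1, ], fm$values[2, ])
  fm2 <- compute_feature_matrix(ts, feature_catalogue(), cfg)
  expect_identical(fm$values, fm2$values)

  # constant region: distribution features error -> whole columns flagged
  ts$values[3, ] <- 1
  fmc <- compute_feature_matrix(ts, feature_catalogue(), cfg)
  expect_false(fmc$valid[["acf_lag_02"]])
  expect_false(fmc$valid[["dist_skewness"]])
  expect_false(fmc$valid[["sample_entropy"]])

  short <- regional_ts(ts$values[, 1:100, drop = FALSE], fs = 128)
  expect_error(compute_feature_matrix(short, feature_catalogue(), cfg),
               "too short")
})

test_that("gradient-linked dynamics leave a signature in acf features", {
  rs <- vapply(1:10, function(s) {
    geom <- generate_parcellation(40, seed = s)
    tr <- planted_truth(geom, n_maps = 1, seed = s)
    ts <- generate_timeseries(geom, tr, duration_s = 40, fs = 200,
                              seed = s)
    cfg <- analysis_config(segment_drop_s = 5, segment_use_s = 30)
    fm <- compute_feature_matrix(ts, feature_catalogue(), cfg)
    acf_cols <- grep("^acf_lag", colnames(fm$values), value = TRUE)
    max(abs(vapply(acf_cols, function(cn)
      cor(fm$values[, cn], tr$gradient, method = "spearman"), 0)))
  }, 0)
  expect_gt(median(rs), 0.5)
})

test_that("robust sigmoid normalization has the documented fixed points", {
  set.seed(11)
  x <- rnorm(101)
  m <- matrix(x, ncol = 1)
  out <- sigmoid_normalize(m, axis = "across_regions")
  # median maps to 0.5 before rescale; with symmetric rescale it stays
  # the midpoint ordering-wise: check rank preservation and endpoints
  expect_equal(min(out), 0); expect_equal(max(out), 1)
  expect_equal(rank(out[, 1]), rank(x))
  # pre-rescale value at the median is exactly 0.5
  iqr <- diff(quantile(x, c(0.25, 0.75))) / 1.35
  pre <- 1 / (1 + exp(-(x - median(x)) / iqr))
  expect_equal(unname(pre[which(x == median(x))]), 0.5)

  # zero-IQR slice flagged invalid, not silently passed
  m2 <- cbind(x, rep(3, 101))
  out2 <- sigmoid_normalize(m2, axis = "across_regions")
  expect_equal(attr(out2, "invalid_slices"), c(2L), ignore_attr = TRUE)
  expect_true(all(is.na(out2[, 2])))

  fmx <- feature_matrix(cbind(f1 = x, f2 = rep(1, 101)))
  nf <- sigmoid_normalize(fmx)
  expect_false(nf$valid[["f2"]])
  expect_true(nf$normalized)
})

test_that("feature estimates stabilize with segment length", {
  set.seed(12)
  skip_cat <- feature_catalogue()
  rs <- vapply(1:5, function(s) {
    geom <- generate_parcellation(6, seed = s)
    tr <- planted_truth(geom, n_maps = 1, seed = s)
    ts <- generate_timeseries(geom, tr, duration_s = 35, fs = 128,
                              seed = s)
    st <- segment_stability(ts, lengths_s = c(5, 10, 25, 30), cat = skip_cat)
    st$r[st$prev_length_s == 25] - st$r[st$prev_length_s == 5]
  }, 0)
  expect_gt(mean(rs > 0), 0.5)
  # identical data, identical segments -> r = 1
  geom <- generate_parcellation(4, seed = 1)
  tr <- planted_truth(geom, n_maps = 1, seed = 1)
  ts <- generate_timeseries(geom, tr, duration_s = 25, fs = 128, seed = 1)
  fm1 <- compute_feature_matrix(ts, skip_cat,
                                analysis_config(segment_drop_s = 0,
                                                segment_use_s = 20))
  fm2 <- compute_feature_matrix(ts, skip_cat,
                                analysis_config(segment_drop_s = 0,
                                                segment_use_s = 20))
  expect_equal(cor(fm1$values[1, ], fm2$values[1, ]), 1)
})
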