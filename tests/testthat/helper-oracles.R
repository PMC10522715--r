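# Brute-force reference implementations, written in the most direct loop
# or definitional form available, independent of the package's code paths.

oracle_acf <- function(x, max_lag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  vapply(0:max_lag, function(l) {
    s <- 0
    for (t in 1:(n - l)) s <- s + (x[t] - xb) * (x[t + l] - xb)
    s / denom
  }, 0)
}

oracle_dfa <- function(x, scales, order) {
  prof <- cumsum(x - mean(x))
  n <- length(x)
  Fv <- vapply(scales, function(s) {
    nw <- n %/% s
    res2 <- 0
    for (w in seq_len(nw)) {
      seg <- prof[((w - 1) * s + 1):(w * s)]
      t <- seq_len(s)
      fit <- lm(seg ~ poly(t, order, raw = TRUE))
      res2 <- res2 + sum(residuals(fit)^2)
    }
    sqrt(res2 / (nw * s))
  }, 0)
  fit <- lm(log(Fv) ~ log(scales))
  list(alpha = unname(coef(fit)[2]), F = Fv)
}

oracle_rolling_detrend_acf1 <- function(x, window) {
  n <- length(x)
  nw <- n %/% window
  resid <- c()
  for (w in seq_len(nw)) {
    seg <- x[((w - 1) * window + 1):(w * window)]
    t <- seq_len(window)
    resid <- c(resid, residuals(lm(seg ~ t)))
  }
  oracle_acf(resid, 1)[2]
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  B <- 0; A <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0) return(Inf)
  -log(A / B)
}

# naive direct-DFT Welch estimate (definitional, no FFT)
oracle_welch <- function(x, fs, window_s, overlap) {
  n <- length(x)
  nw <- round(window_s * fs)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nw - 1) / nw))
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  nf <- nw %/% 2
  k <- 0:nf
  acc <- numeric(nf + 1)
  t <- 0:(nw - 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * w
    for (ki in seq_along(k)) {
      X <- sum(seg * exp(-2i * pi * k[ki] * t / nw))
      acc[ki] <- acc[ki] + Mod(X)^2
    }
  }
  p <- acc / length(starts) / (fs * sum(w^2))
  if (nf >= 2) p[2:nf] <- 2 * p[2:nf]
  list(freqs = k * fs / nw, power = p)
}

# Yule-Walker AR coefficients from the biased ACF (closed form)
oracle_ar <- function(x, order) {
  r <- oracle_acf(x, order)
  Rm <- toeplitz(r[1:order])
  phi <- solve(Rm, r[2:(order + 1)])
  list(ar = phi, var_ratio = 1 - sum(phi * r[2:(order + 1)]))
}

# all-pairs differential stability (direct double loop over donors)
oracle_ds <- function(profiles) {
  # profiles: regions x donors matrix (NA where donor lacks the region)
  N <- ncol(profiles)
  vals <- c()
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      ok <- is.finite(profiles[, i]) & is.finite(profiles[, j])
      if (sum(ok) < 3) next
      vals <- c(vals, cor(profiles[ok, i], profiles[ok, j],
                          method = "spearman"))
    }
  }
  mean(vals)
}

# PLS singular triplets via eigen-decompositions of R'R and RR'
oracle_pls_svd <- function(R) {
  m <- ncol(R)
  ev_v <- eigen(t(R) %*% R, symmetric = TRUE)
  ev_u <- eigen(R %*% t(R), symmetric = TRUE)
  S <- sqrt(pmax(ev_v$values, 0))
  V <- ev_v$vectors
  U <- ev_u$vectors[, seq_len(m), drop = FALSE]
  # fix relative signs so that R V = U S
  for (c in seq_len(m)) {
    if (S[c] > 1e-12) {
      u_implied <- R %*% V[, c] / S[c]
      if (sum(u_implied * U[, c]) < 0) U[, c] <- -U[, c]
    }
  }
  list(U = U, S = S, V = V)
}

# Benjamini-Hochberg by hand (step-up over sorted p-values)
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= (1:m) * q / m)))
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[1:k]] <- TRUE
  rejected
}
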