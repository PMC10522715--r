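# Shared fixtures, built in code. Memoized so expensive objects are
# constructed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

geom100 <- function() fixture("geom100", function()
  generate_parcellation(100, seed = 7))

spins500 <- function() fixture("spins500", function()
  generate_spins(geom100(), 500, seed = 11))

# synthesize a series with PSD ~ 1/f^beta by random-phase construction
colored_noise <- function(n, beta) {
  nf <- floor(n / 2)
  f <- 1:(nf - 1)
  amp <- sqrt(f^(-beta))
  X <- complex(modulus = amp, argument = runif(nf - 1, 0, 2 * pi))
  sp <- complex(real = numeric(n))
  sp[2:nf] <- X
  sp[n:(n - nf + 2)] <- Conj(X)
  Re(fft(sp, inverse = TRUE)) / n
}

# one smooth spatially autocorrelated map (uses the ambient RNG stream)
smooth_map_for_test <- function(geom, smoothness_deg) {
  theta <- great_circle_angles(geom)
  sig <- smoothness_deg * pi / 180
  K <- exp(-theta^2 / (2 * sig^2))
  drop(scale(K %*% rnorm(nrow(geom))))
}

# small planted dataset: X (feature-like maps) and Y (micro-architecture
# maps) sharing one latent axis, plus the truth
planted_dataset <- function(R = 100, n_x = 40, n_y = 10, noise_sd = 0.5,
                            n_null_maps = 0, seed = 1) {
  geom <- generate_parcellation(R, seed = 7)
  trY <- planted_truth(geom, n_maps = n_y, n_null_maps = n_null_maps,
                       seed = seed)
  trX <- planted_truth(geom, n_maps = n_x, seed = seed + 10000)
  trX$gradient <- trY$gradient
  list(geom = geom,
       X = generate_maps(geom, trX, noise_sd = noise_sd, seed = seed + 10000),
       Y = generate_maps(geom, trY, noise_sd = noise_sd, seed = seed),
       gradient = trY$gradient, loadings_Y = trY$map_loadings)
}
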