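## Synthetic-data generators. Every generator draws from an offspring
## stream of the master seed so that regenerating one stage never
## perturbs another, and restores the caller's RNG state on exit.

offspring_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a mirrored spherical parcellation
#'
#' Places `n_regions / 2` quasi-uniform points on the unit hemisphere
#' x > 0 (hemisphere L) using a golden-angle lattice with a small seeded
#' perturbation, then mirrors them through x -> -x to produce hemisphere R.
#' Stands in for parcel centroids projected to a sphere.
#'
#' @param n_regions even region count, >= 4.
#' @param seed integer seed.
#'
#' @return A `parcel_geometry` with regions L then R; region k of L mirrors
#'   region k of R.
#' @export
generate_parcellation <- function(n_regions, seed = 1L) {
  if (n_regions %% 2 != 0)
    stop("n_regions must be even (hemisphere mirroring requires pairs)")
  if (n_regions < 4) stop("n_regions must be >= 4")
  nh <- n_regions / 2
  with_seed(offspring_seed(seed, "parcellation"), {
    i <- seq_len(nh)
    x <- (i - 0.5) / nh                 # pole axis = x, so x in (0, 1)
    r <- sqrt(pmax(0, 1 - x^2))
    theta <- i * pi * (3 - sqrt(5))     # golden angle
    y <- r * cos(theta)
    z <- r * sin(theta)
    # seeded jitter in (y, z), renormalized; keep x bounded away from 0
    y <- y + rnorm(nh, sd = 0.02)
    z <- z + rnorm(nh, sd = 0.02)
    x <- pmax(x, 0.02)
    nrm <- sqrt(x^2 + y^2 + z^2)
    xyz_l <- cbind(x, y, z) / nrm
    xyz <- rbind(xyz_l, cbind(-xyz_l[, 1], xyz_l[, 2], xyz_l[, 3]))
    ids <- c(sprintf("L_%03d", i), sprintf("R_%03d", i))
    parcel_geometry(ids, xyz, rep(c("L", "R"), each = nh))
  })
}

#' Plant a latent dynamics/micro-architecture axis
#'
#' Builds the ground truth shared by the map and time-series generators:
#' a smooth, z-scored regional gradient (a kernel-smoothed Gaussian random
#' field with `gradient_smoothness_deg` width -- an intermediate spatial
#' scale, like empirical cortical gradients, rather than a degenerate
#' whole-sphere dipole), one loading per requested map, and
#' per-region aperiodic/periodic spectral parameters that vary along the
#' gradient. The aperiodic exponent, knee frequency and alpha-peak
#' amplitude all increase or decrease smoothly with the gradient, so
#' downstream autocorrelation- and spectrum-derived features inherit the
#' planted axis.
#'
#' @param geom a `parcel_geometry`.
#' @param n_maps number of micro-architectural maps to plant loadings for.
#' @param n_null_maps how many of the `n_maps` (taken from the end) get a
#'   zero loading, i.e. are pure spatial noise.
#' @param gradient_smoothness_deg kernel width of the planted gradient
#'   field, degrees.
#' @param seed integer seed.
#'
#' @return A `planted_truth` object with elements `gradient` (named, zero
#'   mean, unit variance), `map_loadings`, `aperiodic` (data.frame with
#'   offset, knee, chi per region) and `peaks` (data.frame of Gaussian
#'   peak parameters per region; amplitudes in linear power units).
#' @export
planted_truth <- function(geom, n_maps = 10L, n_null_maps = 0L,
                          gradient_smoothness_deg = 30, seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"), n_maps >= 1,
            n_null_maps >= 0, n_null_maps <= n_maps)
  with_seed(offspring_seed(seed, "truth"), {
    g <- drop(smooth_field(geom, gradient_smoothness_deg, n = 1L))
    names(g) <- geom$region_id

    loadings <- rep(c(1, -1), length.out = n_maps) *
      runif(n_maps, 0.7, 1)
    if (n_null_maps > 0)
      loadings[seq(n_maps - n_null_maps + 1L, n_maps)] <- 0

    chi <- pmin(4, pmax(0.5, 2 + 0.35 * g))
    fk <- 10^(log10(15) + 0.15 * g)     # knee frequency, Hz
    knee <- fk^chi
    offset <- 1 + 0.1 * g               # log10 power units
    aperiodic <- data.frame(region_id = geom$region_id,
                            offset = offset, knee = knee, chi = chi,
                            stringsAsFactors = FALSE)

    # alpha peak scaled relative to the local aperiodic power at its center,
    # amplitude growing along the gradient; fixed modest beta peak
    alpha_c <- 10 + 0.5 * g
    alpha_rel <- pmax(0, 1 + 0.5 * g)
    alpha_amp <- alpha_rel * 10^offset / (knee + alpha_c^chi)
    beta_c <- rep(20, length(g))
    beta_amp <- 0.4 * 10^offset / (knee + beta_c^chi)
    peaks <- rbind(
      data.frame(region_id = geom$region_id, center = alpha_c,
                 amplitude = alpha_amp, width = 1.5,
                 stringsAsFactors = FALSE),
      data.frame(region_id = geom$region_id, center = beta_c,
                 amplitude = beta_amp, width = 3,
                 stringsAsFactors = FALSE))

    structure(list(gradient = g, map_loadings = loadings,
                   aperiodic = aperiodic, peaks = peaks, seed = seed),
              class = "planted_truth")
  })
}

## Smooth spatially autocorrelated field: kernel-weighted i.i.d. noise.
smooth_field <- function(geom, smoothness_deg, n = 1L) {
  if (smoothness_deg <= 0) stop("smoothness must be positive (degrees)")
  theta <- great_circle_angles(geom)
  sig <- smoothness_deg * pi / 180
  K <- exp(-theta^2 / (2 * sig^2))
  w <- matrix(rnorm(nrow(theta) * n), nrow(theta), n)
  eps <- K %*% w
  scale(eps)                            # zero mean, unit variance per column
}

#' Generate a planted micro-architectural map set
#'
#' Each map is `loading * gradient` plus a smooth spatially autocorrelated
#' noise field (kernel-weighted independent Gaussian noise with kernel
#' `exp(-theta^2 / (2 * smoothness^2))` over inter-region great-circle
#' angles), scaled to `noise_sd`; columns are z-scored.
#'
#' @param geom a `parcel_geometry`.
#' @param truth a `planted_truth` whose `map_loadings` sets the map count.
#' @param smoothness_deg kernel width of the noise field, degrees.
#' @param noise_sd standard deviation of the smooth noise component
#'   relative to the unit-variance gradient.
#' @param seed integer seed.
#'
#' @return A `brain_maps` object with z-scored columns.
#' @export
generate_maps <- function(geom, truth, smoothness_deg = 20, noise_sd = 0.5,
                          seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"),
            inherits(truth, "planted_truth"))
  if (smoothness_deg <= 0) stop("smoothness must be positive (degrees)")
  n_maps <- length(truth$map_loadings)
  with_seed(offspring_seed(seed, "maps"), {
    eps <- smooth_field(geom, smoothness_deg, n = n_maps)
    m <- outer(truth$gradient, truth$map_loadings) + noise_sd * eps
    m <- scale(m)
    brain_maps(m, map_name = sprintf("map_%02d", seq_len(n_maps)),
               region_id = geom$region_id)
  })
}

## One-sided target PSD (power per Hz) of the generating model.
model_psd <- function(f, offset, knee, chi, peaks = NULL) {
  p <- 10^offset / (knee + f^chi)
  if (!is.null(peaks) && nrow(peaks) > 0)
    for (i in seq_len(nrow(peaks)))
      p <- p + peaks$amplitude[i] *
        exp(-(f - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  p
}

## Random-phase spectral synthesis of one series from a one-sided PSD.
synth_from_psd <- function(psd_fun, n, fs) {
  nf <- floor(n / 2)
  f <- (1:(nf - 1)) * fs / n
  amp <- sqrt(psd_fun(f) * fs * n / 2)
  phase <- runif(nf - 1, 0, 2 * pi)
  X <- complex(modulus = amp, argument = phase)
  spec <- complex(real = numeric(n))
  spec[2:nf] <- X
  spec[n:(n - nf + 2)] <- Conj(X)
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate regional signals with planted spectra
#'
#' Synthesizes each regional signal by inverse Fourier transform of
#' amplitudes `sqrt(PSD(f))` with i.i.d. uniform random phases, where the
#' target one-sided PSD is the knee-form aperiodic component plus the
#' region's Gaussian oscillatory peaks:
#' `PSD(f) = 10^offset / (knee + f^chi) + sum A exp(-(f - c)^2 / (2 w^2))`.
#' The generating PSD is therefore known in closed form, which makes the
#' spectral-fit stage testable against ground truth.
#'
#' @param geom a `parcel_geometry`.
#' @param truth a `planted_truth`.
#' @param duration_s signal length in seconds (>= 10).
#' @param fs sampling rate in Hz; must exceed 4x the highest peak center.
#' @param seed integer seed.
#'
#' @return A `regional_ts`.
#' @export
generate_timeseries <- function(geom, truth, duration_s = 110, fs = 509,
                                seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"),
            inherits(truth, "planted_truth"))
  if (duration_s < 10) stop("duration must be >= 10 s")
  pk_max <- if (nrow(truth$peaks)) max(truth$peaks$center) else 0
  if (pk_max >= fs / 2) stop("peak center at or above the Nyquist frequency")
  if (fs < 4 * pk_max) stop("fs must be at least 4x the highest peak center")
  n <- round(duration_s * fs)
  with_seed(offspring_seed(seed, "timeseries"), {
    vals <- matrix(0, nrow(geom), n)
    for (r in seq_len(nrow(geom))) {
      ap <- truth$aperiodic[r, ]
      pk <- truth$peaks[truth$peaks$region_id == geom$region_id[r], ]
      vals[r, ] <- synth_from_psd(function(f)
        model_psd(f, ap$offset, ap$knee, ap$chi, pk), n, fs)
    }
    regional_ts(vals, fs = fs, region_id = geom$region_id)
  })
}

#' Generate a toy forward model
#'
#' Places `n_sensors` quasi-uniformly on a sphere of radius 1.2 and models
#' the per-sensor field of a unit source at each region as an
#' inverse-square falloff with source-sensor distance; sources sit at a
#' seeded depth below the unit sphere, so deeper sources produce smaller
#' total gain. Sensor noise variances are positive and heterogeneous.
#'
#' @param geom a `parcel_geometry`.
#' @param n_sensors sensor count (>= 1).
#' @param seed integer seed.
#' @param a source amplitude in nAm (default 10, a typical dipole strength).
#' @param source_radius optional per-region radial position in (0, 1]; by
#'   default drawn uniformly in [0.8, 1].
#'
#' @return A `forward_model`: list with `a`, `gains` (sensors x regions),
#'   `noise_var` (per sensor), `sensor_xyz`, `source_radius`.
#' @export
generate_forward_model <- function(geom, n_sensors = 64L, seed = 1L,
                                   a = 10, source_radius = NULL) {
  stopifnot(inherits(geom, "parcel_geometry"))
  if (n_sensors < 1) stop("n_sensors must be >= 1")
  with_seed(offspring_seed(seed, "forward"), {
    i <- seq_len(n_sensors)
    zs <- if (n_sensors == 1) 0 else (2 * i - n_sensors - 1) / n_sensors
    rs <- sqrt(pmax(0, 1 - zs^2))
    th <- i * pi * (3 - sqrt(5))
    sensor_xyz <- 1.2 * cbind(rs * cos(th), rs * sin(th), zs)
    if (is.null(source_radius))
      source_radius <- runif(nrow(geom), 0.8, 1)
    src <- geometry_xyz(geom) * source_radius
    d2 <- outer(rowSums(sensor_xyz^2), rowSums(src^2), "+") -
      2 * sensor_xyz %*% t(src)
    gains <- 1 / d2                     # inverse-square falloff
    noise_var <- runif(n_sensors, 0.5, 1.5)
    structure(list(a = a, gains = gains, noise_var = noise_var,
                   sensor_xyz = sensor_xyz, source_radius = source_radius,
                   region_id = geom$region_id),
              class = "forward_model")
  })
}

#' Generate a toy multi-donor microarray bundle
#'
#' Emulates a post-mortem microarray data set at toy scale: per donor,
#' tissue samples are placed at jittered region coordinates with the left
#' hemisphere over-represented (to exercise bilateral mirroring); each
#' gene has one "good" probe tracking a smooth spatial profile shared
#' across donors plus donor noise, and optionally additional noisy probes;
#' above-background flags are set per probe x sample.
#'
#' @param geom a `parcel_geometry`.
#' @param n_donors number of donors (>= 2).
#' @param n_genes number of genes.
#' @param probes_per_gene probes per gene (>= 1); probe 1 is the good one.
#' @param truth a `planted_truth`; roughly half of the genes track its
#'   gradient, the rest follow independent smooth profiles.
#' @param seed integer seed.
#' @param donor_noise_sd donor-level noise SD on expression values.
#' @param below_background_rate probability a good-probe measurement is
#'   flagged below background; noisy probes use three times this rate.
#' @param samples_per_donor samples per donor (default ~80% of regions).
#'
#' @return An `expression_bundle`: list with `intensity` (probes x
#'   samples), `probe_id`, `probe_gene`, `above_background`,
#'   `sample_donor`, `sample_xyz`, `sample_hemisphere`, plus the ground
#'   truth `gene_profile` (regions x genes) and `sample_region`.
#' @export
generate_expression_bundle <- function(geom, n_donors = 4L, n_genes = 30L,
                                       probes_per_gene = 2L, truth,
                                       seed = 1L, donor_noise_sd = 0.3,
                                       below_background_rate = 0.1,
                                       samples_per_donor = NULL) {
  stopifnot(inherits(geom, "parcel_geometry"),
            inherits(truth, "planted_truth"))
  if (n_donors < 2) stop("n_donors must be >= 2")
  if (probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  R <- nrow(geom)
  if (is.null(samples_per_donor)) samples_per_donor <- ceiling(0.8 * R)
  with_seed(offspring_seed(seed, "expression"), {
    n_grad <- ceiling(n_genes / 2)
    prof <- matrix(0, R, n_genes)
    coefs <- rep(c(0.8, -0.8), length.out = n_grad)
    smooth <- smooth_field(geom, smoothness_deg = 25, n = n_genes)
    for (j in seq_len(n_genes)) {
      prof[, j] <- if (j <= n_grad)
        coefs[j] * truth$gradient + 0.4 * smooth[, j]
      else smooth[, j]
    }
    ## bilaterally symmetric profiles (the assumption that justifies
    ## mirroring samples across hemispheres downstream)
    xyz <- geometry_xyz(geom)
    mirror <- apply(cbind(-xyz[, 1], xyz[, 2], xyz[, 3]) %*% t(xyz),
                    1, which.max)
    prof <- (prof + prof[mirror, , drop = FALSE]) / 2
    rownames(prof) <- geom$region_id
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    colnames(prof) <- genes

    # left hemisphere over-represented in sampling
    p_reg <- ifelse(geom$hemisphere == "L", 3, 1)
    sample_region <- integer(0); sample_donor <- character(0)
    for (d in seq_len(n_donors)) {
      reg <- sample.int(R, samples_per_donor, replace = FALSE,
                        prob = p_reg / sum(p_reg))
      sample_region <- c(sample_region, reg)
      sample_donor <- c(sample_donor, rep(sprintf("donor%d", d),
                                          samples_per_donor))
    }
    ns <- length(sample_region)
    sample_xyz <- geometry_xyz(geom)[sample_region, , drop = FALSE] +
      matrix(rnorm(3 * ns, sd = 0.03), ns, 3)
    sample_hemisphere <- geom$hemisphere[sample_region]

    n_probes <- n_genes * probes_per_gene
    probe_gene <- rep(genes, each = probes_per_gene)
    probe_id <- sprintf("%s_p%d", probe_gene,
                        rep(seq_len(probes_per_gene), n_genes))
    intensity <- matrix(0, n_probes, ns,
                        dimnames = list(probe_id, NULL))
    rate <- matrix(0, n_probes, ns)
    for (p in seq_len(n_probes)) {
      j <- match(probe_gene[p], genes)
      good <- (p - 1) %% probes_per_gene == 0
      base <- prof[sample_region, j] +
        rnorm(ns, sd = donor_noise_sd)
      if (good) {
        intensity[p, ] <- base
        rate[p, ] <- below_background_rate
      } else {
        intensity[p, ] <- 0.3 * base + rnorm(ns, sd = 2 * donor_noise_sd + 0.5)
        rate[p, ] <- min(1, 3 * below_background_rate)
      }
    }
    above_background <- matrix(runif(n_probes * ns) >= rate, n_probes, ns,
                               dimnames = list(probe_id, NULL))
    structure(list(intensity = intensity, probe_id = probe_id,
                   probe_gene = probe_gene,
                   above_background = above_background,
                   sample_donor = sample_donor, sample_xyz = sample_xyz,
                   sample_hemisphere = sample_hemisphere,
                   sample_region = geom$region_id[sample_region],
                   gene_profile = prof),
              class = "expression_bundle")
  })
}
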