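# Synthetic voxel data with planted frequency-specific networks, 1/f
# background, white noise, and optional phase-amplitude coupling — with full
# ground truth, so every pipeline stage is testable without real recordings.

#' Define a planted network
#'
#' A fixed spatial loading vector (unit maximum) paired with a narrowband
#' oscillatory source: Gaussian white noise filtered to a Gaussian spectral
#' bump at `center_frequency` with the given FWHM `bandwidth`, scaled to RMS
#' `amplitude`. Filtered noise (rather than a pure sinusoid) keeps the Hilbert
#' phase non-degenerate, which matters for realistic phase-amplitude coupling.
#'
#' @param loading numeric loading vector (will be scaled to max 1), or `NULL`
#'   to place a Gaussian blob at simulation time (see [simulate_dataset()]).
#' @param center_frequency source center frequency (Hz).
#' @param bandwidth source spectral FWHM (Hz); default follows
#'   [fwhm_schedule()] so planted sources match the scanning filters.
#' @param amplitude source RMS in voxel units (default 2: twice the default
#'   background RMS).
#' @param blob_center optional lattice-coordinate center for the default blob
#'   (fraction of each axis, in `[0, 1]^3`).
#' @param blob_sigma_mm blob standard deviation in mm.
#' @return An object of class `planted_network`.
#' @export
planted_network <- function(loading = NULL, center_frequency,
                            bandwidth = fwhm_schedule(center_frequency),
                            amplitude = 2, blob_center = NULL,
                            blob_sigma_mm = 12) {
  stopifnot(center_frequency > 0, bandwidth > 0, amplitude >= 0)
  if (!is.null(loading)) {
    loading <- as.numeric(loading)
    if (max(abs(loading)) == 0) stop("loading is identically zero")
    loading <- loading / max(abs(loading))
  }
  structure(list(loading = loading, center_frequency = center_frequency,
                 bandwidth = bandwidth, amplitude = amplitude,
                 blob_center = blob_center, blob_sigma_mm = blob_sigma_mm),
            class = "planted_network")
}

#' Define a simulation
#'
#' Study-condition defaults: 200 voxels on an 8-mm 3-D lattice, 120 s at
#' 250 Hz, two planted networks at distinct alpha/beta-range grid frequencies
#' (9.6 and 24 Hz) with non-overlapping blobs, source RMS twice the 1/f
#' background RMS, and unit white sensor noise.
#'
#' @param n_voxels number of voxels.
#' @param duration_s recording length (s).
#' @param sampling_rate sampling rate (Hz).
#' @param networks list of [planted_network()] objects.
#' @param aperiodic_exponent exponent beta of the 1/f^beta background.
#' @param background_rms per-voxel RMS of the 1/f background.
#' @param white_noise_rms per-voxel RMS of the white noise.
#' @param pac optional list `(modulator, carrier, kappa)`: indices into
#'   `networks` and a coupling depth in `[0, 1]`. The carrier source is
#'   multiplied by `(1 + kappa * sin(phase_mod)) / (1 + kappa)`, with
#'   `phase_mod` the modulator source's Hilbert phase, so its mean power stays
#'   approximately kappa-invariant.
#' @param grid_spacing_mm lattice spacing (mm).
#' @param seed RNG seed (mandatory).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_voxels = 200, duration_s = 120,
                            sampling_rate = 250,
                            networks = list(
                              planted_network(center_frequency = 9.6,
                                              blob_center = c(0.25, 0.25, 0.5)),
                              planted_network(center_frequency = 24,
                                              blob_center = c(0.75, 0.75, 0.5))),
                            aperiodic_exponent = 1, background_rms = 1,
                            white_noise_rms = 1, pac = NULL,
                            grid_spacing_mm = 8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  nyq <- sampling_rate / 2
  for (nw in networks) {
    if (nw$center_frequency >= nyq) {
      stop("network at ", nw$center_frequency, " Hz is at or above Nyquist (",
           nyq, " Hz)")
    }
  }
  if (!is.null(pac)) {
    stopifnot(all(c("modulator", "carrier", "kappa") %in% names(pac)))
    if (pac$kappa < 0 || pac$kappa > 1) stop("kappa must lie in [0, 1]")
    stopifnot(pac$modulator != pac$carrier,
              pac$modulator <= length(networks),
              pac$carrier <= length(networks))
  }
  stopifnot(background_rms >= 0, white_noise_rms >= 0)
  structure(list(n_voxels = n_voxels, duration_s = duration_s,
                 sampling_rate = sampling_rate, networks = networks,
                 aperiodic_exponent = aperiodic_exponent,
                 background_rms = background_rms,
                 white_noise_rms = white_noise_rms, pac = pac,
                 grid_spacing_mm = grid_spacing_mm, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Near-cubic axis-aligned lattice of n points with the given spacing (mm).
lattice_coordinates <- function(n, spacing = 8) {
  k <- ceiling(n^(1 / 3))
  dims <- c(k, k, ceiling(n / k^2))
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  as.matrix(g[seq_len(n), ]) * spacing
}

gaussian_blob <- function(coords, center_frac, sigma_mm) {
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  ctr <- lo + center_frac * (hi - lo)
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  v <- exp(-d2 / (2 * sigma_mm^2))
  v / max(v)
}

scale_rms <- function(x, rms) {
  s <- sqrt(mean(x^2))
  if (s == 0 || rms == 0) return(x * 0)
  x * (rms / s)
}

# Narrowband source: white noise filtered to a Gaussian spectral bump.
narrowband_source <- function(T, fs, center, bandwidth, rms) {
  kern <- design_gaussian_kernel(center, bandwidth, T, fs)
  scale_rms(filter_vector(rnorm(T), kern), rms)
}

# 1/f^beta noise by spectral shaping of white noise.
aperiodic_noise <- function(T, fs, beta, rms) {
  z <- stats::fft(rnorm(T))
  f <- (0:(T - 1)) * fs / T
  f <- pmin(f, fs - f)
  g <- c(0, f[-1]^(-beta / 2))
  scale_rms(Re(stats::fft(z * g, inverse = TRUE) / T), rms)
}

#' Simulate a voxel dataset with known ground truth
#'
#' Generates `X = L S + B + E`: planted narrowband network sources `S` mixed
#' through their spatial loadings `L`, per-voxel 1/f aperiodic background `B`,
#' and per-voxel white noise `E`. With phase-amplitude coupling requested, the
#' carrier source is gain-modulated by the modulator source's Hilbert phase
#' before mixing. Identical spec and seed give a bit-identical dataset.
#'
#' @param spec a [simulation_spec()].
#' @return List with `dataset` (a [voxel_dataset()]) and `truth` (loadings
#'   matrix, source time series (post-coupling), network definitions, pac
#'   settings, modulator phase if pac was planted).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  T <- round(spec$duration_s * spec$sampling_rate)
  n <- spec$n_voxels
  fs <- spec$sampling_rate
  coords <- lattice_coordinates(n, spec$grid_spacing_mm)
  K <- length(spec$networks)
  L <- matrix(0, n, max(K, 1))
  sources <- matrix(0, max(K, 1), T)
  defaults_centers <- list(c(0.25, 0.25, 0.5), c(0.75, 0.75, 0.5),
                           c(0.5, 0.25, 0.25), c(0.25, 0.75, 0.75))
  for (k in seq_len(K)) {
    nw <- spec$networks[[k]]
    L[, k] <- if (!is.null(nw$loading)) {
      if (length(nw$loading) != n) stop("loading length differs from n_voxels")
      nw$loading
    } else {
      ctr <- if (!is.null(nw$blob_center)) nw$blob_center else
        defaults_centers[[(k - 1) %% length(defaults_centers) + 1]]
      gaussian_blob(coords, ctr, nw$blob_sigma_mm)
    }
    sources[k, ] <- narrowband_source(T, fs, nw$center_frequency,
                                      nw$bandwidth, nw$amplitude)
  }
  phase_mod <- NULL
  if (!is.null(spec$pac) && spec$pac$kappa > 0) {
    kappa <- spec$pac$kappa
    phase_mod <- Arg(analytic_signal(sources[spec$pac$modulator, ]))
    gain <- (1 + kappa * sin(phase_mod)) / (1 + kappa)
    sources[spec$pac$carrier, ] <- sources[spec$pac$carrier, ] * gain
  }
  X <- if (K > 0) L %*% sources else matrix(0, n, T)
  if (spec$background_rms > 0) {
    for (v in seq_len(n)) {
      X[v, ] <- X[v, ] + aperiodic_noise(T, fs, spec$aperiodic_exponent,
                                         spec$background_rms)
    }
  }
  if (spec$white_noise_rms > 0) {
    X <- X + matrix(rnorm(n * T, sd = spec$white_noise_rms), n, T)
  }
  ds <- voxel_dataset(X, sampling_rate = fs, coordinates = coords,
                      grid_spacing_mm = spec$grid_spacing_mm)
  list(dataset = ds,
       truth = list(loadings = L[, seq_len(K), drop = FALSE],
                    sources = sources[seq_len(K), , drop = FALSE],
                    networks = spec$networks, pac = spec$pac,
                    phase_mod = phase_mod))
}

#' Simulate a paired two-condition group
#'
#' Per subject, two datasets (baseline condition `"RS"` and effect condition
#' `"PL"`) share spatial loadings and subject-level amplitude jitter but draw
#' independent noise; the effect condition additionally applies the stated
#' deltas — typically adding a network attuned to the stimulation frequency
#' and/or raising the phase-amplitude coupling depth.
#'
#' @param spec_base a [simulation_spec()] describing the baseline condition.
#' @param n_subjects number of subjects (>= 5).
#' @param condition_effect list with any of: `add_network` (a
#'   [planted_network()] appended in the effect condition), `kappa_delta`
#'   (added to the pac depth), `amplitude_scale` (multiplier on all planted
#'   amplitudes in the effect condition).
#' @param amplitude_jitter_sd log-normal sd of per-subject amplitude jitter.
#' @param loading_jitter_sd sd of additive per-subject loading jitter
#'   (re-scaled to max 1).
#' @param seed group-level seed; per-subject seeds are derived from it.
#' @return List of `n_subjects` elements, each with `RS` and `PL`
#'   [voxel_dataset()]s and the per-condition ground truths.
#' @export
simulate_group <- function(spec_base, n_subjects = 26,
                           condition_effect = list(), amplitude_jitter_sd = 0.2,
                           loading_jitter_sd = 0.1, seed) {
  stopifnot(inherits(spec_base, "simulation_spec"), n_subjects >= 5)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  subj_seeds <- sample.int(2^31 - 1, 2 * n_subjects)
  jitters <- exp(rnorm(n_subjects, sd = amplitude_jitter_sd))
  out <- vector("list", n_subjects)
  coords <- lattice_coordinates(spec_base$n_voxels, spec_base$grid_spacing_mm)
  for (s in seq_len(n_subjects)) {
    nets <- spec_base$networks
    # freeze per-subject loadings so RS and PL share them
    set.seed(subj_seeds[2 * s - 1])
    for (k in seq_along(nets)) {
      base_load <- if (!is.null(nets[[k]]$loading)) nets[[k]]$loading else
        gaussian_blob(coords,
                      if (!is.null(nets[[k]]$blob_center)) nets[[k]]$blob_center
                      else c(0.25 + 0.5 * ((k - 1) %% 2), 0.25, 0.5),
                      nets[[k]]$blob_sigma_mm)
      jl <- base_load + rnorm(length(base_load), sd = loading_jitter_sd)
      nets[[k]]$loading <- jl / max(abs(jl))
      nets[[k]]$amplitude <- nets[[k]]$amplitude * jitters[s]
    }
    spec_rs <- spec_base
    spec_rs$networks <- nets
    spec_rs$seed <- subj_seeds[2 * s - 1]

    nets_pl <- nets
    if (!is.null(condition_effect$amplitude_scale)) {
      for (k in seq_along(nets_pl)) {
        nets_pl[[k]]$amplitude <- nets_pl[[k]]$amplitude *
          condition_effect$amplitude_scale
      }
    }
    pac_pl <- spec_base$pac
    if (!is.null(condition_effect$add_network)) {
      nw <- condition_effect$add_network
      if (is.null(nw$loading)) {
        bl <- gaussian_blob(coords,
                            if (!is.null(nw$blob_center)) nw$blob_center
                            else c(0.5, 0.5, 0.5), nw$blob_sigma_mm)
        nw$loading <- bl
      }
      nw$amplitude <- nw$amplitude * jitters[s]
      nets_pl <- c(nets_pl, list(nw))
    }
    if (!is.null(condition_effect$kappa_delta)) {
      if (is.null(pac_pl)) stop("kappa_delta requires pac in spec_base")
      pac_pl$kappa <- min(1, pac_pl$kappa + condition_effect$kappa_delta)
    }
    spec_pl <- spec_base
    spec_pl$networks <- nets_pl
    spec_pl$pac <- pac_pl
    spec_pl$seed <- subj_seeds[2 * s]

    sim_rs <- simulate_dataset(spec_rs)
    sim_pl <- simulate_dataset(spec_pl)
    id <- sprintf("s%02d", s)
    sim_rs$dataset$subject_id <- id; sim_rs$dataset$condition <- "RS"
    sim_pl$dataset$subject_id <- id; sim_pl$dataset$condition <- "PL"
    out[[s]] <- list(RS = sim_rs$dataset, PL = sim_pl$dataset,
                     truth_RS = sim_rs$truth, truth_PL = sim_pl$truth)
  }
  names(out) <- sprintf("s%02d", seq_len(n_subjects))
  out
}
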