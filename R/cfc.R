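# Phase-amplitude cross-frequency coupling between network time series.
#
# The modulator's instantaneous phase and each carrier's instantaneous power
# come from narrowband-filtered network activation time series (the same
# Gaussian kernels used for the decomposition), via the analytic signal.

#' Instantaneous phase of a network time series
#'
#' Narrowband filters the series with the given kernel and returns the angle
#' of its analytic signal, in radians within (-pi, pi].
#'
#' @param y a [network_timeseries()] (or plain numeric vector).
#' @param kernel [design_gaussian_kernel()] matching the series length and
#'   sampling rate (typically at the modulator frequency).
#' @return Phase vector in radians.
#' @export
extract_phase <- function(y, kernel) {
  v <- if (inherits(y, "network_timeseries")) y$values else as.numeric(y)
  check_kernel_vs_series(y, kernel, length(v))
  z <- analytic_signal(filter_vector(v, kernel))
  if (all(Mod(z) < 1e-12 * max(1, stats::sd(v)))) {
    stop("degenerate input: analytic signal has (near-)zero magnitude everywhere")
  }
  Arg(z)
}

#' Instantaneous power of a network time series
#'
#' Squared magnitude of the analytic signal of the narrowband-filtered series.
#'
#' @inheritParams extract_phase
#' @return Non-negative power vector (carrier amplitude units squared).
#' @export
extract_power <- function(y, kernel) {
  v <- if (inherits(y, "network_timeseries")) y$values else as.numeric(y)
  check_kernel_vs_series(y, kernel, length(v))
  Mod(analytic_signal(filter_vector(v, kernel)))^2
}

# Internal helpers -----------------------------------------------------------

filter_vector <- function(v, kernel) {
  n <- length(v)
  Re(stats::fft(stats::fft(v) * kernel$gains, inverse = TRUE) / n)
}

check_kernel_vs_series <- function(y, kernel, n) {
  if (kernel$n_samples != n) {
    stop("kernel built for ", kernel$n_samples, " samples; series has ", n)
  }
  if (inherits(y, "network_timeseries") &&
      kernel$sampling_rate != y$sampling_rate) {
    stop("kernel sampling rate differs from the series")
  }
}

#' Mean carrier power per modulator phase bin
#'
#' Divides the phase axis (-180, 180] degrees into `n_bins` left-closed,
#' right-open bins of equal width starting at -180 degrees and averages the
#' carrier power within each. Empty bins are filled by circular linear
#' interpolation between their non-empty neighbors; more than 25% empty bins
#' is an error (recording too short for the modulator frequency).
#'
#' @param phase modulator phase, radians in (-pi, pi].
#' @param power carrier power, same length.
#' @param n_bins number of phase bins (>= 4; 36 bins of 10 degrees in the
#'   standard configuration).
#' @return Numeric vector of length `n_bins`; attribute `bin_centers` holds
#'   the bin centers in degrees (-175, ..., +175 for 36 bins).
#' @export
power_over_phase <- function(phase, power, n_bins = 36) {
  if (length(phase) != length(power)) stop("phase/power lengths differ")
  if (n_bins < 4) stop("need at least 4 bins")
  deg <- phase * 180 / pi
  deg[deg >= 180] <- deg[deg >= 180] - 360   # fold +180 onto -180
  width <- 360 / n_bins
  idx <- pmin(floor((deg + 180) / width) + 1, n_bins)
  bin_power <- rep(NA_real_, n_bins)
  agg <- tapply(power, factor(idx, levels = seq_len(n_bins)), mean)
  bin_power[] <- as.numeric(agg)
  empty <- is.na(bin_power)
  if (mean(empty) > 0.25) {
    stop(sum(empty), "/", n_bins,
         " empty phase bins: recording too short for this modulator frequency")
  }
  if (any(empty)) bin_power <- fill_circular(bin_power)
  centers <- -180 + width * (seq_len(n_bins) - 0.5)
  attr(bin_power, "bin_centers") <- centers
  bin_power
}

# Circular linear interpolation over NA runs.
fill_circular <- function(v) {
  n <- length(v)
  ok <- which(!is.na(v))
  for (i in which(is.na(v))) {
    d_prev <- (i - ok) %% n
    d_next <- (ok - i) %% n
    p <- ok[which.min(replace(d_prev, d_prev == 0, n))]
    q <- ok[which.min(replace(d_next, d_next == 0, n))]
    dp <- (i - p) %% n; dq <- (q - i) %% n
    v[i] <- (v[p] * dq + v[q] * dp) / (dp + dq)
  }
  v
}

#' Fit a one-cycle sine to a power-over-phase distribution
#'
#' Least-squares fit of `A sin(theta + phi) + c` with the period fixed to one
#' cycle over the phase axis, solved in closed form by projection onto the
#' sin/cos/constant basis. The amplitude is reported non-negative (a negative
#' fit is folded into the phase) and serves as the modulation-strength index.
#'
#' @param bin_power numeric vector of mean powers per bin.
#' @param bin_centers bin centers in degrees; defaults to the
#'   `"bin_centers"` attribute of `bin_power`.
#' @return List with `amplitude` (>= 0), `phase_deg` in (-180, 180], and
#'   `offset`.
#' @export
fit_sine <- function(bin_power, bin_centers = attr(bin_power, "bin_centers")) {
  if (is.null(bin_centers)) stop("bin_centers missing")
  if (length(bin_power) != length(bin_centers)) stop("length mismatch")
  if (!all(is.finite(bin_power))) stop("bin_power must be finite")
  th <- bin_centers * pi / 180
  X <- cbind(sin(th), cos(th), 1)
  b <- qr.solve(X, as.numeric(bin_power))
  amplitude <- sqrt(b[1]^2 + b[2]^2)
  phase <- if (amplitude > 0) atan2(b[2], b[1]) * 180 / pi else 0
  list(amplitude = unname(amplitude), phase_deg = unname(phase),
       offset = unname(b[3]))
}

#' Scan carriers for phase-amplitude coupling with one modulator
#'
#' For one low-frequency modulator component, computes the power-over-phase
#' distribution and sine-fit modulation strength of the first (or chosen)
#' component at every higher carrier frequency. Modulator phase and carrier
#' power are taken from network activation time series reconstructed with the
#' landscape's spatial filters; both are narrowband filtered with the same
#' Gaussian kernels used in the scan. One second at each edge is discarded
#' before binning to suppress filter/Hilbert edge transients.
#'
#' @param broad broadband [voxel_dataset()] the landscape was computed from.
#' @param landscape a [scan_frequencies()] result for `broad`.
#' @param modulator_frequency modulator center frequency (must be a grid
#'   center; default the grid's stimulation frequency).
#' @param modulator_component modulator component rank (1-based).
#' @param carrier_component carrier component rank (default 1).
#' @param carrier_frequencies carrier centers; default all grid centers
#'   strictly above the modulator frequency.
#' @param n_bins number of phase bins.
#' @return Data frame with one row per carrier: `modulator_frequency`,
#'   `modulator_component`, `carrier_frequency`, `carrier_component`,
#'   `strength`, `fit_phase_deg`, `fit_offset`; attribute `"profiles"` holds
#'   the per-carrier `modulation_profile` objects (bin powers and fits).
#' @export
cfc_scan <- function(broad, landscape, modulator_frequency = NULL,
                     modulator_component = 1, carrier_component = 1,
                     carrier_frequencies = NULL, n_bins = 36) {
  stopifnot(inherits(landscape, "freqness_landscape"))
  grid <- landscape$grid
  if (is.null(modulator_frequency)) {
    modulator_frequency <- grid$stimulation_frequency
  }
  if (is.null(modulator_frequency)) stop("no modulator frequency given")
  im <- match_center(grid, modulator_frequency)
  if (is.null(carrier_frequencies)) {
    carrier_frequencies <- grid$centers[grid$centers > modulator_frequency]
  }
  if (any(carrier_frequencies <= modulator_frequency)) {
    stop("carrier frequencies must lie strictly above the modulator frequency")
  }
  T <- ncol(broad$data)
  fs <- broad$sampling_rate
  guard <- seq_len(T)
  edge <- round(fs)
  if (T > 2 * edge + n_bins) guard <- (edge + 1):(T - edge)

  w_mod <- landscape$decompositions[[im]]$filters[, modulator_component]
  y_mod <- component_timeseries(w_mod, broad,
                                frequency = grid$centers[im],
                                component_index = modulator_component)
  kern_mod <- design_gaussian_kernel(grid$centers[im], grid$fwhms[im], T, fs)
  phase <- extract_phase(y_mod, kern_mod)[guard]

  profiles <- vector("list", length(carrier_frequencies))
  rows <- vector("list", length(carrier_frequencies))
  for (j in seq_along(carrier_frequencies)) {
    ic <- match_center(grid, carrier_frequencies[j])
    w_car <- landscape$decompositions[[ic]]$filters[, carrier_component]
    y_car <- component_timeseries(w_car, broad,
                                  frequency = grid$centers[ic],
                                  component_index = carrier_component)
    kern_car <- design_gaussian_kernel(grid$centers[ic], grid$fwhms[ic], T, fs)
    pw <- extract_power(y_car, kern_car)[guard]
    bp <- power_over_phase(phase, pw, n_bins = n_bins)
    fit <- fit_sine(bp)
    profiles[[j]] <- structure(
      list(modulator_frequency = grid$centers[im],
           modulator_component = modulator_component,
           carrier_frequency = grid$centers[ic],
           carrier_component = carrier_component,
           bin_power = bp, bin_centers = attr(bp, "bin_centers"),
           sine_fit = fit, modulation_strength = fit$amplitude),
      class = "modulation_profile")
    rows[[j]] <- data.frame(modulator_frequency = grid$centers[im],
                            modulator_component = modulator_component,
                            carrier_frequency = grid$centers[ic],
                            carrier_component = carrier_component,
                            strength = fit$amplitude,
                            fit_phase_deg = fit$phase_deg,
                            fit_offset = fit$offset)
  }
  out <- do.call(rbind, rows)
  out$subject <- broad$subject_id
  out$condition <- broad$condition
  attr(out, "profiles") <- profiles
  out
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("<modulation_profile> %g Hz (comp %d) phase -> %g Hz (comp %d) power: strength %.4g\n",
              x$modulator_frequency, x$modulator_component,
              x$carrier_frequency, x$carrier_component,
              x$modulation_strength))
  invisible(x)
}

match_center <- function(grid, f) {
  i <- which(abs(grid$centers - f) < 1e-9)
  if (length(i) != 1) stop("frequency ", f, " Hz is not a grid center")
  i
}
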