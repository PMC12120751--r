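#' Build the default frequency scanning grid
#'
#' The grid consists of `n_below` frequencies below the stimulation frequency,
#' the stimulation frequency itself, and the ladder
#' `stimulation_frequency + k * step_above` for k = 1, 2, ... while the result
#' stays at or below `f_max`. With the defaults (stimulation 2.4 Hz, step
#' 1.2 Hz, ceiling 97.6 Hz, six sub-stimulation centers) this yields 86
#' centers starting at 0.2 Hz, with every second center above the stimulation
#' frequency an exact integer multiple of it (harmonics interleaved with
#' half-harmonics). Filter widths follow [fwhm_schedule()].
#'
#' The sub-stimulation centers are ambiguous under any single spacing rule, so
#' they are configurable; the default is an ascending 0.2 Hz-spaced series
#' anchored at 0.2 Hz.
#'
#' @param stimulation_frequency stimulation frequency (Hz).
#' @param f_max grid ceiling (Hz); the ladder stops at the last center <= f_max.
#' @param step_above spacing above the stimulation frequency (Hz).
#' @param n_below number of centers below the stimulation frequency.
#' @param sub_stim_centers optional explicit sub-stimulation centers
#'   (overrides `n_below`).
#' @param fwhm_base filter FWHM at the stimulation frequency (Hz).
#' @param fwhm_slope log10-linear FWHM slope, see [fwhm_schedule()].
#' @param sampling_rate optional; if given, centers must lie below Nyquist.
#' @return A [frequency_grid()].
#' @examples
#' g <- build_frequency_grid()
#' length(g)          # 86
#' range(g$centers)
#' @export
build_frequency_grid <- function(stimulation_frequency = 2.4, f_max = 97.6,
                                 step_above = 1.2, n_below = 6,
                                 sub_stim_centers = NULL, fwhm_base = 0.3,
                                 fwhm_slope = 1, sampling_rate = NULL) {
  stopifnot(stimulation_frequency > 0, step_above > 0, f_max >= stimulation_frequency)
  if (is.null(sub_stim_centers)) {
    sub_stim_centers <- if (n_below > 0) seq(0.2, by = 0.2, length.out = n_below) else numeric(0)
  }
  if (any(sub_stim_centers >= stimulation_frequency)) {
    stop("sub-stimulation centers must lie below the stimulation frequency")
  }
  k_max <- floor((f_max - stimulation_frequency) / step_above + 1e-9)
  above <- if (k_max >= 1) stimulation_frequency + seq_len(k_max) * step_above else numeric(0)
  centers <- c(sub_stim_centers, stimulation_frequency, above)
  fwhms <- fwhm_schedule(centers, base_fwhm_at_stim = fwhm_base,
                         stimulation_frequency = stimulation_frequency,
                         slope = fwhm_slope)
  frequency_grid(centers, fwhms,
                 stimulation_frequency = stimulation_frequency,
                 sampling_rate = sampling_rate)
}

#' Filter bandwidth schedule over the frequency scan
#'
#' Full width at half maximum of the narrowband filter as a log10-linear
#' function of center frequency, anchored at the stimulation frequency:
#' `fwhm(f) = base * 10^(slope * (log10(f) - log10(f_stim)))`. The default
#' slope 1 gives constant relative bandwidth (FWHM proportional to frequency),
#' the standard wavelet convention; slope 0 gives a constant width.
#'
#' @param center center frequency (Hz), vectorized.
#' @param base_fwhm_at_stim FWHM at the stimulation frequency (Hz).
#' @param stimulation_frequency anchor frequency (Hz).
#' @param slope log10-linear slope (dimensionless).
#' @return FWHM in Hz, same length as `center`.
#' @examples
#' fwhm_schedule(2.4)        # 0.3
#' fwhm_schedule(24, slope = 1)  # 3.0
#' @export
fwhm_schedule <- function(center, base_fwhm_at_stim = 0.3,
                          stimulation_frequency = 2.4, slope = 1) {
  stopifnot(all(center > 0), base_fwhm_at_stim > 0, stimulation_frequency > 0)
  base_fwhm_at_stim * 10^(slope * (log10(center) - log10(stimulation_frequency)))
}

#' Design a frequency-domain Gaussian wavelet kernel
#'
#' Gaussian gain `G(f) = exp(-4 ln 2 (f - center)^2 / fwhm^2)` evaluated at
#' the FFT bin frequencies of an `n_samples`-long signal, mirrored onto the
#' negative-frequency bins (Hermitian symmetry, guaranteeing real filtered
#' output) and normalized to peak gain 1 at the bin nearest the center.
#'
#' @param center center frequency (Hz), strictly inside (0, Nyquist).
#' @param fwhm full width at half maximum gain (Hz).
#' @param n_samples signal length the kernel is built for.
#' @param sampling_rate sampling rate (Hz).
#' @return An object of class `gaussian_kernel` with elements `gains`
#'   (length `n_samples`), `center_frequency`, `fwhm`, `n_samples`,
#'   `sampling_rate`.
#' @export
design_gaussian_kernel <- function(center, fwhm, n_samples, sampling_rate) {
  stopifnot(n_samples >= 16, fwhm > 0)
  nyq <- sampling_rate / 2
  if (center <= 0 || center >= nyq) {
    stop("center must lie strictly between 0 and Nyquist (", nyq, " Hz)")
  }
  df <- sampling_rate / n_samples
  if (fwhm < df) {
    warning(sprintf("kernel under-resolved: fwhm %.4g Hz narrower than one FFT bin (%.4g Hz)",
                    fwhm, df))
  }
  k <- 0:(n_samples - 1)
  f <- k * df
  f_pos <- pmin(f, sampling_rate - f)  # two-sided mirror
  gains <- exp(-4 * log(2) * (f_pos - center)^2 / fwhm^2)
  gains <- gains / max(gains)
  structure(list(gains = gains, center_frequency = center, fwhm = fwhm,
                 n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate),
            class = "gaussian_kernel")
}

#' @export
print.gaussian_kernel <- function(x, ...) {
  cat(sprintf("<gaussian_kernel> center %g Hz, fwhm %g Hz, %d bins at %g Hz\n",
              x$center_frequency, x$fwhm, x$n_samples, x$sampling_rate))
  invisible(x)
}

# Internal: filter the rows of a numeric matrix with a gain vector over FFT
# bins. Pairs of real rows are packed into one complex signal (the gain vector
# is real and symmetric, so the real and imaginary parts remain exactly
# separated), halving the FFT count.
filter_matrix_rows <- function(X, gains, block = 256L) {
  n <- nrow(X); T <- ncol(X)
  stopifnot(length(gains) == T)
  out <- matrix(0, n, T)
  i <- 1L
  while (i <= n) {
    # take up to 2*block rows -> block complex columns
    last <- min(n, i + 2L * block - 1L)
    rows <- i:last
    npair <- ceiling(length(rows) / 2)
    Z <- matrix(0i, T, npair)
    for (j in seq_len(npair)) {
      r1 <- rows[2L * j - 1L]
      z <- X[r1, ]
      if (2L * j <= length(rows)) z <- z + 1i * X[rows[2L * j], ]
      Z[, j] <- z
    }
    Z <- stats::mvfft(Z)
    Z <- Z * gains                       # column-major recycling over bins
    Z <- stats::mvfft(Z, inverse = TRUE) / T
    for (j in seq_len(npair)) {
      out[rows[2L * j - 1L], ] <- Re(Z[, j])
      if (2L * j <= length(rows)) out[rows[2L * j], ] <- Im(Z[, j])
    }
    i <- last + 1L
  }
  out
}

#' Narrowband filter a voxel dataset
#'
#' Each voxel row is forward-FFT'd, multiplied element-wise by the kernel
#' gains, and inverse-FFT'd. The operation is linear and returns real output
#' (the kernel is Hermitian-symmetric). No windowing or segmentation is
#' applied: the full epoch is filtered in one pass.
#'
#' @param dataset a [voxel_dataset()].
#' @param kernel a [design_gaussian_kernel()] built for this dataset's length
#'   and sampling rate.
#' @return A [narrowband_dataset()].
#' @export
narrowband_filter <- function(dataset, kernel) {
  stopifnot(inherits(dataset, "voxel_dataset"),
            inherits(kernel, "gaussian_kernel"))
  if (kernel$n_samples != ncol(dataset$data) ||
      kernel$sampling_rate != dataset$sampling_rate) {
    stop("kernel was built for ", kernel$n_samples, " samples at ",
         kernel$sampling_rate, " Hz; dataset has ", ncol(dataset$data),
         " samples at ", dataset$sampling_rate, " Hz")
  }
  filt <- filter_matrix_rows(dataset$data, kernel$gains)
  narrowband_dataset(dataset, filt, kernel$center_frequency, kernel$fwhm)
}

#' Analytic signal via the Hilbert transform
#'
#' Returns `x + i H(x)` computed in the frequency domain (zeroing negative
#' frequencies, doubling positive ones). Instantaneous phase is `Arg()` of the
#' result and instantaneous power its squared modulus.
#'
#' @param x real numeric vector, length >= 16.
#' @return Complex vector of the same length; its real part equals `x`.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  n <- length(x)
  if (n < 16) stop("need at least 16 samples")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  # force the real part to equal the input exactly
  complex(real = x, imaginary = Im(z))
}
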