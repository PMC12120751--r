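# Shared fixtures, all generated in code.

# Small white-noise dataset.
noise_dataset <- function(n_voxels = 10, duration_s = 10, fs = 250, seed = 1,
                          with_coords = FALSE) {
  set.seed(seed)
  T <- duration_s * fs
  coords <- if (with_coords) freqness:::lattice_coordinates(n_voxels, 8) else NULL
  voxel_dataset(matrix(rnorm(n_voxels * T), n_voxels, T), sampling_rate = fs,
                coordinates = coords, grid_spacing_mm = if (with_coords) 8 else NULL)
}

# A sinusoid with an integer number of cycles in the window.
sinusoid <- function(freq, duration_s = 10, fs = 250, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  cos(2 * pi * freq * t + phase)
}

# Reduced scanning grid for fast end-to-end tests.
small_grid <- function(centers = c(2.4, 4.8, 9.6, 14.4, 24), fs = 250) {
  frequency_grid(centers, fwhm_schedule(centers),
                 stimulation_frequency = 2.4, sampling_rate = fs)
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign assignments of
# the observed absolute differences (mid-ranked). Independent oracle for the
# normal approximation.
wilcoxon_exact_p <- function(diffs, tail = "two") {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (tail == "two") {
    mean(abs(W_all - mu) >= abs(W_obs - mu))
  } else {
    mean(W_all >= W_obs)
  }
}

# Spectral (eigendecomposition) inverse square root of R: an independent
# route to the generalized eigenproblem, used as oracle for solve_ged.
ged_whitening_oracle <- function(S, R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  Rinv_half <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  M <- Rinv_half %*% S %*% Rinv_half
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Rinv_half %*% es$vectors
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  list(eigenvalues = es$values, filters = W)
}

# Width between the two 0.5-gain crossings around the peak of a sampled
# frequency response (linear interpolation between bins).
measure_fwhm <- function(f, gains) {
  i_pk <- which.max(gains)
  cross <- function(idx) {
    for (i in idx) {
      a <- gains[i]; b <- gains[i + 1]
      if ((a - 0.5) * (b - 0.5) <= 0 && a != b) {
        return(f[i] + (0.5 - a) / (b - a) * (f[i + 1] - f[i]))
      }
    }
    NA_real_
  }
  lo <- cross(rev(seq_len(i_pk - 1)))
  hi <- cross(seq(i_pk, length(gains) - 1))
  hi - lo
}

wrap_diff <- function(d) {
  ((d + pi) %% (2 * pi)) - pi
}

random_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 4)), n)
  crossprod(t(A)) / (n + 4) + diag(0.1, n)
}
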