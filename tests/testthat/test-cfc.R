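test_that("phase extraction wraps correctly and rejects degenerate input", {
  fs <- 250; dur <- 30
  y <- network_timeseries(sinusoid(2.4, dur, fs), 2.4, 1, fs)
  k <- design_gaussian_kernel(2.4, 0.3, dur * fs, fs)
  ph <- extract_phase(y, k)
  expect_true(all(ph > -pi & ph <= pi))
  # phase advances 2*pi per cycle
  core <- (fs + 1):(dur * fs - fs)
  slope <- mean(wrap_diff(diff(ph[core]))) * fs / (2 * pi)
  expect_equal(slope, 2.4, tolerance = 0.01)
  # phase histogram of a pure sinusoid is uniform over 36 bins
  h <- table(cut(ph[core], breaks = seq(-pi, pi, length.out = 37)))
  expect_lt(max(abs(h - mean(h))) / mean(h), 0.05)
  expect_error(extract_phase(network_timeseries(rep(0, dur * fs), 2.4, 1, fs), k),
               "degenerate")
})

test_that("power is the squared analytic modulus and scales quadratically", {
  fs <- 250; dur <- 20
  y <- sinusoid(10, dur, fs)
  k <- design_gaussian_kernel(10, 1, dur * fs, fs)
  pw <- extract_power(y, k)
  core <- (fs + 1):(dur * fs - fs)
  expect_equal(pw[core], rep(1, length(core)), tolerance = 1e-3)
  expect_equal(extract_power(3 * y, k), 9 * pw, tolerance = 1e-9)
  expect_equal(extract_power(0 * y, k), rep(0, dur * fs))
})

test_that("power-over-phase bins reproduce an analytic sinusoidal modulation", {
  set.seed(12)
  phase <- runif(2e5, -pi, pi)
  power <- rep(1, length(phase))
  bp <- power_over_phase(phase, power)
  expect_length(bp, 36)
  expect_equal(attr(bp, "bin_centers"), seq(-175, 175, by = 10))
  expect_equal(as.numeric(bp), rep(1, 36))
  power2 <- 1 + 0.5 * sin(phase)
  bp2 <- power_over_phase(phase, power2)
  expect_equal(as.numeric(bp2), 1 + 0.5 * sin(attr(bp2, "bin_centers") * pi / 180),
               tolerance = 0.01)
})

test_that("sparse phase coverage triggers interpolation then an error", {
  # phase confined to (-pi/2, pi/2): half the bins empty -> error
  expect_error(power_over_phase(runif(500, -pi / 2, pi / 2), rep(1, 500)),
               "empty phase bins")
  # one empty bin is interpolated from its neighbors
  phase <- seq(-pi + 0.01, pi - 0.01, length.out = 3600)
  drop <- abs(phase * 180 / pi - 0) > 5  # empty the bin centered at +5 deg
  bp <- power_over_phase(phase[drop], (2 + cos(phase))[drop])
  expect_true(all(is.finite(bp)))
})

test_that("sine fit is exact on noiseless data and matches a lattice search", {
  th <- seq(-175, 175, by = 10)
  bp <- 2 * sin((th + 30) * pi / 180) + 5
  fit <- fit_sine(bp, th)
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$phase_deg, 30, tolerance = 1e-9)
  expect_equal(fit$offset, 5, tolerance = 1e-9)
  flat <- fit_sine(rep(7, 36), th)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$offset, 7)
  # brute-force lattice oracle
  set.seed(3)
  bp2 <- 1.3 * sin((th - 80) * pi / 180) + 2 + rnorm(36, sd = 0.05)
  fit2 <- fit_sine(bp2, th)
  lattice <- expand.grid(A = seq(0.5, 2.5, by = 0.02),
                         phi = seq(-180, 179, by = 1),
                         c = seq(1.5, 2.5, by = 0.02))
  sse <- function(A, phi, c0)
    sum((bp2 - (A * sin((th + phi) * pi / 180) + c0))^2)
  best <- lattice[which.min(mapply(sse, lattice$A, lattice$phi, lattice$c)), ]
  expect_equal(fit2$amplitude, best$A, tolerance = 0.02)
  expect_equal(fit2$phase_deg, best$phi, tolerance = 1.5)
  expect_equal(fit2$offset, best$c, tolerance = 0.02)
})

test_that("sine amplitude recovery degrades gracefully under noise", {
  th <- seq(-175, 175, by = 10)
  set.seed(8)
  reps <- replicate(50, fit_sine(3 * sin((th + 10) * pi / 180) + 1 +
                                   rnorm(36, sd = 0.1), th)$amplitude)
  # linear-model standard error of the sine coefficient: sigma / sqrt(18)
  expect_lt(max(abs(reps - 3)), 3 * 0.1 / sqrt(18) * 3)
})

test_that("modulation strength ignores offsets and rotates with the bins", {
  th <- seq(-175, 175, by = 10)
  bp <- 1.7 * sin((th - 40) * pi / 180) + 3
  f0 <- fit_sine(bp, th)
  f1 <- fit_sine(bp + 11.5, th)
  expect_equal(f0$amplitude, f1$amplitude, tolerance = 1e-12)
  # circular rotation of bins shifts the fitted phase, not the amplitude
  rot <- c(bp[10:36], bp[1:9])
  f2 <- fit_sine(rot, th)
  expect_equal(f2$amplitude, f0$amplitude, tolerance = 1e-9)
  expect_equal((f2$phase_deg - f0$phase_deg) %% 360, (10 - 1) * 10,
               tolerance = 1e-6)
})

test_that("cfc_scan flags a planted phase-amplitude coupled carrier", {
  carriers <- c(19.2, 40.8, 60, 79.2, 96)
  grid <- frequency_grid(c(2.4, carriers), fwhm_schedule(c(2.4, carriers)),
                         stimulation_frequency = 2.4)
  run <- function(kappa, seed) {
    nets <- list(planted_network(center_frequency = 2.4, amplitude = 3,
                                 blob_center = c(0.25, 0.25, 0.5)),
                 planted_network(center_frequency = 79.2, amplitude = 3,
                                 blob_center = c(0.75, 0.75, 0.5)))
    spec <- simulation_spec(n_voxels = 40, duration_s = 60, networks = nets,
                            pac = list(modulator = 1, carrier = 2,
                                       kappa = kappa), seed = seed)
    sim <- simulate_dataset(spec)
    lsc <- scan_frequencies(sim$dataset, grid, n_keep = 2)
    cfc_scan(sim$dataset, lsc, modulator_frequency = 2.4)
  }
  cf <- run(0.8, 21)
  s_pl <- cf$strength[cf$carrier_frequency == 79.2]
  expect_gt(s_pl, 5 * median(cf$strength[cf$carrier_frequency != 79.2]))
  # carriers must lie above the modulator
  spec <- simulation_spec(n_voxels = 40, duration_s = 60, seed = 1)
  sim <- simulate_dataset(spec)
  lsc <- scan_frequencies(sim$dataset, grid, n_keep = 1)
  expect_error(cfc_scan(sim$dataset, lsc, modulator_frequency = 2.4,
                        carrier_frequencies = c(2.4, 19.2)),
               "strictly above")
})
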