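test_that("covariances follow the mean-centered cross-product definition", {
  # 2-voxel hand example: each row is (1, -1, 0, ..., 0); row means are zero,
  # so centering changes nothing and R = X X' = [[2, 2], [2, 2]]
  M <- matrix(0, 2, 600)
  M[, 1] <- 1; M[, 2] <- -1
  broad <- voxel_dataset(M, 250)
  narrow <- narrowband_dataset(broad, M, 2.4, 0.3)
  pair <- suppressWarnings(
    compute_covariances(broad, narrow, gamma_S = 0, gamma_R_fraction = 0))
  expect_equal(pair$R, matrix(2, 2, 2))
  # narrow == broad -> S == R before regularization
  expect_equal(pair$S, pair$R)
  # zero regularization leaves raw covariances untouched
  pair2 <- compute_covariances(broad, narrow, gamma_S = 1e-6,
                               gamma_R_fraction = 0.01)
  expect_equal(pair2$S - diag(1e-6, 2), pair$S)
  expect_equal(pair2$R, pair$R + diag(0.01 * sum(diag(pair$R)) / 2, 2))
  expect_error(compute_covariances(broad, matrix(0, 3, 600)), "shapes differ")
})

test_that("solve_ged handles decoupled and degenerate cases", {
  # diagonal pair: independent 1-D problems
  sol <- solve_ged(list(S = diag(c(4, 1)), R = diag(c(2, 1))))
  expect_equal(sol$eigenvalues, c(2, 1))
  expect_equal(abs(sol$filters), diag(2), tolerance = 1e-12)
  # S = R: flat spectrum, all normalized eigenvalues equal
  R <- random_spd(6, 20)
  solf <- solve_ged(list(S = R, R = R))
  expect_equal(solf$eigenvalues, rep(1, 6), tolerance = 1e-10)
  expect_equal(normalize_eigenvalues(solf$eigenvalues), rep(100 / 6, 6))
})

test_that("solve_ged matches the spectral whitening oracle on random SPD pairs", {
  worst <- 0
  for (i in 1:100) {
    n <- sample(2:20, 1)
    S <- random_spd(n, 1000 + i)
    R <- random_spd(n, 2000 + i)
    sol <- solve_ged(list(S = S, R = R))
    ora <- ged_whitening_oracle(S, R)
    rel <- max(abs(sol$eigenvalues - ora$eigenvalues) /
                 pmax(abs(ora$eigenvalues), 1e-12))
    worst <- max(worst, rel)
    # filter directions agree up to sign
    align <- abs(colSums(sol$filters * ora$filters))
    expect_true(all(align > 1 - 1e-6))
  }
  expect_lt(worst, 1e-8)
})

test_that("normalized eigenvalues are percentages summing to 100", {
  expect_equal(normalize_eigenvalues(c(3, 1)), c(75, 25))
  expect_equal(normalize_eigenvalues(rep(1, 4)), rep(25, 4))
  set.seed(9)
  lam <- sort(rexp(30), decreasing = TRUE)
  expect_equal(sum(normalize_eigenvalues(lam)), 100, tolerance = 1e-9)
  expect_error(normalize_eigenvalues(c(0, 0)), "all eigenvalues are zero")
  expect_error(normalize_eigenvalues(c(1, -1)), "non-negative")
})

test_that("component time series is the filtered projection of centered data", {
  d <- noise_dataset(5, 4, 250, seed = 31)
  e1 <- c(1, 0, 0, 0, 0)
  y <- component_timeseries(e1, d)
  expect_equal(y$values, d$data[1, ] - mean(d$data[1, ]))
  y3 <- component_timeseries(3 * e1, d)
  expect_equal(y3$values, 3 * y$values)
  expect_error(component_timeseries(c(1, 2), d), "does not match")
})

test_that("activation patterns are |S w| scaled to unit maximum", {
  w <- c(0.2, -0.8, 0.5)
  a <- activation_pattern(w, diag(3))
  expect_equal(a, abs(w) / 0.8)
  expect_equal(max(a), 1)
  expect_true(min(a) >= 0)
  expect_error(activation_pattern(c(1, 0), matrix(0, 2, 2)), "identically zero")
})

test_that("display threshold selects mean + 1 sd exceedances", {
  expect_equal(sum(threshold_pattern_for_display(rep(0.5, 20))), 0)
  a <- c(1, rep(0, 99))   # mean 0.01, sd 0.1, threshold 0.11
  expect_equal(which(threshold_pattern_for_display(a)), 1L)
  set.seed(2)
  b <- runif(50)
  expect_identical(threshold_pattern_for_display(b),
                   threshold_pattern_for_display(7.3 * b))
})

test_that("PCA backend equals GED with identity reference and catches rank-1 data", {
  d <- noise_dataset(6, 6, 250, seed = 40)
  k <- design_gaussian_kernel(10, 1, ncol(d$data), 250)
  nb <- narrowband_filter(d, k)
  pca <- pca_decomposition(nb, n_keep = 6)
  Xn <- nb$data - rowMeans(nb$data)
  S <- tcrossprod(Xn)
  ged_id <- solve_ged(list(S = S, R = diag(nrow(S))))
  expect_equal(pca$eigenvalues, ged_id$eigenvalues, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))
  # rank-1 narrowband data -> first component takes ~all the variance
  src <- sinusoid(10, 6, 250)
  M <- outer(c(1, 2, -1, 0.5), src) + matrix(rnorm(4 * 1500, sd = 1e-4), 4)
  d1 <- voxel_dataset(M, 250)
  nb1 <- narrowband_filter(d1, design_gaussian_kernel(10, 1, 1500, 250))
  p1 <- pca_decomposition(nb1, n_keep = 4)
  expect_gt(p1$normalized_eigenvalues[1], 99)
})

test_that("scan recovers planted networks in frequency, space, and time", {
  # a single planted 10 Hz-range network is the global eigenspectrum argmax
  spec1 <- simulation_spec(n_voxels = 60, duration_s = 60,
                           networks = list(planted_network(center_frequency = 9.6,
                                                           amplitude = 2)),
                           seed = 19)
  sim1 <- simulate_dataset(spec1)
  g <- build_frequency_grid(sampling_rate = 250)
  t1 <- scan_frequencies(sim1$dataset, g, n_keep = 1)$table
  expect_equal(t1$frequency[which.max(t1$eigenvalue_pct)], 9.6,
               tolerance = 1e-9)
  # two networks: each planted bin is a strict local eigenspectrum peak with
  # faithful spatial and temporal recovery (the lowest bins carry a high
  # baseline from their ultra-narrow filters, as in real 1/f landscapes)
  spec <- simulation_spec(n_voxels = 100, duration_s = 60, seed = 42)
  sim <- simulate_dataset(spec)
  ls1 <- scan_frequencies(sim$dataset, g, n_keep = 3)
  tab <- ls1$table[ls1$table$component == 1, ]
  planted <- vapply(spec$networks, `[[`, numeric(1), "center_frequency")
  for (i in seq_along(planted)) {
    j <- which(abs(g$centers - planted[i]) < 1e-9)
    expect_gt(tab$eigenvalue_pct[j], tab$eigenvalue_pct[j - 1])
    expect_gt(tab$eigenvalue_pct[j], tab$eigenvalue_pct[j + 1])
    expect_gt(tab$eigenvalue_pct[j], 3 * median(tab$eigenvalue_pct))
    dec <- ls1$decompositions[[j]]
    expect_gt(cor(dec$patterns[, 1], abs(sim$truth$loadings[, i])), 0.95)
    y <- component_timeseries(dec$filters[, 1], sim$dataset)
    expect_gt(abs(cor(y$values, sim$truth$sources[i, ])), 0.9)
  }
  # landscape table invariants
  expect_true(all(tapply(ls1$table$eigenvalue_pct,
                         ls1$table$frequency,
                         function(v) all(diff(v) <= 1e-9))))
})

test_that("white-noise eigenspectrum is roughly flat and n_keep is honored", {
  d <- noise_dataset(30, 20, 250, seed = 55)
  g <- small_grid()
  ls1 <- scan_frequencies(d, g, n_keep = 1)
  expect_equal(nrow(ls1$table), length(g$centers))
  top <- ls1$table$eigenvalue_pct
  expect_lt(sd(top) / mean(top), 0.5)
})

test_that("normalized eigenvalues are invariant to global rescaling of the data", {
  d <- noise_dataset(8, 6, 250, seed = 66)
  g <- small_grid(c(9.6, 24))
  l1 <- scan_frequencies(d, g, n_keep = 8)
  d2 <- d; d2$data <- d$data * 7.7
  l2 <- scan_frequencies(d2, g, n_keep = 8)
  expect_equal(l1$table$eigenvalue_pct, l2$table$eigenvalue_pct,
               tolerance = 1e-6)
})
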