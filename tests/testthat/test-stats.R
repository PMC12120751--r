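test_that("signed-rank approximation tracks the exact distribution", {
  # extreme case: all 26 differences positive
  res <- wilcoxon_signed_rank(rep(1, 26) + runif(26), tail = "right")
  expect_lt(res$p, 1e-5)
  expect_gt(res$z, 4)
  # symmetric differences: z = 0, p = 1
  res0 <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # all sign patterns at n = 8 against enumeration: the default (exact for
  # small n) agrees to machine precision; the normal approximation's known
  # worst-case deviation is 0.0201 (two-tailed, at W = 11)
  set.seed(17)
  mags <- runif(8, 0.5, 2)
  worst_def <- 0; worst_norm <- 0
  for (bits in 0:255) {
    signs <- ifelse(bitwAnd(bits, 2^(0:7)) > 0, 1, -1)
    d <- mags * signs
    for (tail in c("two", "right")) {
      p_ex <- wilcoxon_exact_p(d, tail = tail)
      worst_def <- max(worst_def,
                       abs(wilcoxon_signed_rank(d, tail = tail)$p - p_ex))
      worst_norm <- max(worst_norm,
                        abs(wilcoxon_signed_rank(d, tail = tail,
                                                 method = "normal")$p - p_ex))
    }
  }
  expect_lt(worst_def, 0.02)
  expect_lt(worst_norm, 0.021)
  expect_warning(wilcoxon_signed_rank(rep(0, 6)), "all differences are zero")
})

test_that("signed-rank agrees with the base-R reference implementation", {
  set.seed(23)
  for (i in 1:20) {
    d <- rnorm(26, mean = 0.3)
    p_pkg <- wilcoxon_signed_rank(d)$p
    p_ref <- wilcox.test(d, correct = TRUE, exact = FALSE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-8)
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adjusted, rep(0.04, 4))
  expect_true(all(r$mask))
  expect_false(any(fdr_bh(rep(1, 10))$mask))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster permutation finds a planted contiguous effect", {
  # 26 subjects x 30 bins; bins 11-14 carry a 1-sd shift
  gen <- function(seed) {
    set.seed(seed)
    D <- matrix(rnorm(26 * 30), 26, 30)
    D[, 11:14] <- D[, 11:14] + 1
    D
  }
  hits <- 0
  for (r in 1:20) {
    cl <- cluster_permutation(gen(400 + r), n_perm = 1000, seed = 500 + r)
    ok <- any(cl$size >= 4 & cl$p_cluster < 0.01 & cl$start <= 11 & cl$end >= 14)
    hits <- hits + ok
  }
  expect_gte(hits, 18)  # >= 90% of runs
})

test_that("cluster permutation respects its structural guarantees", {
  set.seed(9)
  D <- matrix(rnorm(20 * 15), 20, 15)
  cl <- cluster_permutation(D, n_perm = 1000, seed = 2)
  if (nrow(cl)) expect_true(all(cl$p_cluster >= 1 / 1001))
  # no bin past the forming threshold -> empty result
  cl0 <- cluster_permutation(D, n_perm = 1000, seed = 3,
                             alpha_cluster_forming = 1e-6)
  expect_equal(nrow(cl0), 0)
  # global label flip mirrors z and leaves cluster p unchanged
  D1 <- matrix(rnorm(20 * 15), 20, 15) + 0.8
  c_a <- suppressWarnings(cluster_permutation(D1, n_perm = 500, seed = 7))
  c_b <- suppressWarnings(cluster_permutation(-D1, n_perm = 500, seed = 7))
  expect_equal(attr(c_a, "bin_z"), -attr(c_b, "bin_z"))
  expect_equal(c_a$p_cluster, c_b$p_cluster)
  expect_warning(cluster_permutation(D1, n_perm = 200, seed = 1), "coarse")
})

test_that("FDR-significant cell rate stays at or below q under the global null", {
  set.seed(77)
  n_cells <- 40
  rate <- replicate(100, {
    D <- matrix(rnorm(26 * n_cells), 26, n_cells)
    res <- freqness:::signed_rank_columns(D)
    mean(fdr_bh(res$p)$mask)
  })
  expect_lte(mean(rate), 0.05 + 0.01)
})

test_that("landscape contrast flags the planted condition difference only", {
  # identical inputs -> nothing significant
  tab <- expand.grid(subject = sprintf("s%02d", 1:10), condition = "RS",
                     frequency = c(2.4, 4.8), component = 1:3,
                     stringsAsFactors = FALSE)
  set.seed(5)
  tab <- tab[order(tab$subject, tab$condition, tab$frequency, tab$component), ]
  tab$eigenvalue_pct <- as.numeric(
    replicate(20, sort(runif(3, 1, 5), decreasing = TRUE)))
  same <- landscape_contrast(tab, tab, components = 1:3)
  expect_false(any(same$significant))
  expect_true(all(same$p_raw == 1))
  # planted increase at one (frequency, component) cell
  tabB <- tab
  sel <- tab$frequency == 2.4 & tab$component == 1
  tabA <- tab
  tabA$eigenvalue_pct[sel] <- tabA$eigenvalue_pct[sel] + 3
  res <- landscape_contrast(tabA, tabB, components = 1:3)
  hit <- res[res$frequency == 2.4 & res$component == 1, ]
  expect_true(hit$significant)
  expect_gt(hit$z, 0)        # A > B gives positive z (network emergence)
  expect_false(any(res$significant[!(res$frequency == 2.4 & res$component == 1)]))
  # subject mismatch is reported
  expect_error(landscape_contrast(tabA, tabB[tabB$subject != "s03", ]),
               "s03")
})

test_that("modulation contrast is right-tailed and directional", {
  set.seed(6)
  mk <- function(shift) {
    g <- expand.grid(subject = sprintf("s%02d", 1:12),
                     carrier_frequency = c(60, 70, 80), stringsAsFactors = FALSE)
    g$strength <- runif(nrow(g), 1, 2) +
      ifelse(g$carrier_frequency == 80, shift, 0)
    g
  }
  base <- mk(0)
  up <- base; up$strength <- up$strength + ifelse(up$carrier_frequency == 80, 2, 0)
  res <- modulation_contrast(up, base)
  expect_true(res$significant[res$frequency == 80])
  expect_false(any(res$significant[res$frequency != 80]))
  # swapping A and B kills a positive effect under the right tail
  res_sw <- modulation_contrast(base, up)
  expect_false(any(res_sw$significant))
  expect_false(any(modulation_contrast(base, base)$significant))
})
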