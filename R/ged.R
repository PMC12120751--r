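# Internal: mean-center matrix rows in place (C++) or by sweep for copies.
center_rows <- function(X) X - rowMeans(X)

#' Narrowband and broadband covariance pair
#'
#' Mean-centers every voxel row over time, forms the raw cross-product
#' covariances `S = Xn Xn'` (narrowband) and `R = Xb Xb'` (broadband; no
#' 1/(T-1) factor — the normalized eigenvalues are invariant to it), and
#' regularizes: `S <- S + gamma_S I` and
#' `R <- R + gamma_R_fraction * mean(eig(R)) I`, with the mean eigenvalue of R
#' taken as `trace(R)/n`.
#'
#' @param broad broadband [voxel_dataset()].
#' @param narrow matching [narrowband_dataset()] (same dimensions).
#' @param gamma_S additive diagonal constant for S.
#' @param gamma_R_fraction fraction of R's mean eigenvalue added to its
#'   diagonal.
#' @return An object of class `covariance_pair` with elements `S`, `R`,
#'   `gamma_S`, `gamma_R_fraction`.
#' @export
compute_covariances <- function(broad, narrow, gamma_S = 1e-6,
                                gamma_R_fraction = 0.01) {
  stopifnot(inherits(broad, "voxel_dataset"))
  Xn <- if (inherits(narrow, "voxel_dataset")) narrow$data else as.matrix(narrow)
  Xb <- broad$data
  if (!identical(dim(Xb), dim(Xn))) stop("broad and narrow shapes differ")
  Xb <- center_rows(Xb)
  Xn <- center_rows(Xn)
  v <- rowSums(Xb^2)
  if (any(v == 0)) warning("zero-variance voxel(s): ",
                           paste(head(which(v == 0)), collapse = ", "))
  S <- tcrossprod(Xn)
  R <- tcrossprod(Xb)
  n <- nrow(S)
  S <- S + diag(gamma_S, n)
  R <- R + diag(gamma_R_fraction * sum(diag(R)) / n, n)
  structure(list(S = S, R = R, gamma_S = gamma_S,
                 gamma_R_fraction = gamma_R_fraction),
            class = "covariance_pair")
}

# Internal: sign convention — flip each filter column so the largest-magnitude
# entry of its activation pattern (S w) is positive.
fix_signs <- function(W, S) {
  P <- S %*% W
  for (k in seq_len(ncol(W))) {
    j <- which.max(abs(P[, k]))
    if (P[j, k] < 0) W[, k] <- -W[, k]
  }
  W
}

#' Solve the regularized generalized eigenproblem S w = lambda R w
#'
#' Whitens by the Cholesky factor of R and solves the resulting symmetric
#' eigenproblem, so all eigenvalues are real and (up to round-off)
#' non-negative. Filters (columns of W) are scaled to unit Euclidean norm and
#' sign-fixed so that the largest-magnitude entry of each activation pattern
#' `S w` is positive. Eigenvalues are returned sorted descending.
#'
#' @param pair a [compute_covariances()] result, or any list with symmetric
#'   matrices `S` and `R` (R positive definite).
#' @param values_only if `TRUE`, skip the eigenvectors (faster for large
#'   problems where only the eigenspectrum is needed).
#' @param chol_R optional precomputed `chol(R)`, reused across frequencies.
#' @return List with `eigenvalues` (descending) and `filters` (`NULL` when
#'   `values_only`).
#' @export
solve_ged <- function(pair, values_only = FALSE, chol_R = NULL) {
  S <- pair$S
  if (!all(is.finite(S))) stop("non-finite entries in S")
  U <- if (is.null(chol_R)) {
    R <- pair$R
    if (!all(is.finite(R))) stop("non-finite entries in R")
    chol(R)
  } else chol_R
  # M = L^-1 S L^-T with R = L L' = U' U
  tmp <- backsolve(U, S, transpose = TRUE)          # L^-1 S
  M <- backsolve(U, t(tmp), transpose = TRUE)       # L^-1 S' L^-T
  M <- (M + t(M)) / 2
  if (values_only) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    return(list(eigenvalues = ev, filters = NULL))
  }
  es <- eigen(M, symmetric = TRUE)
  W <- backsolve(U, es$vectors)                     # w = U^-1 y
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  W <- fix_signs(W, S)
  list(eigenvalues = es$values, filters = W)
}

#' Normalize eigenvalues to percent of total variance
#'
#' `lambda_i * 100 / sum(lambda)`; sums to 100. Eigenvalues must be
#' non-negative up to numerical tolerance (tiny negative round-off is clamped
#' to zero) and not all zero.
#'
#' @param eigenvalues numeric vector.
#' @return Percent vector of the same length.
#' @export
normalize_eigenvalues <- function(eigenvalues) {
  lam <- as.numeric(eigenvalues)
  tol <- 1e-8 * max(abs(lam), 0)
  if (any(lam < -tol)) stop("eigenvalues must be non-negative")
  lam[lam < 0] <- 0
  s <- sum(lam)
  if (s == 0) stop("all eigenvalues are zero")
  lam * 100 / s
}

#' Network activation time series from a spatial filter
#'
#' `y = w' X_broad` on the mean-centered broadband data.
#'
#' @param w spatial filter vector (length `n_voxels`).
#' @param broad broadband [voxel_dataset()].
#' @param frequency,component_index metadata for the resulting series.
#' @return A [network_timeseries()].
#' @export
component_timeseries <- function(w, broad, frequency = NA_real_,
                                 component_index = 1L) {
  stopifnot(inherits(broad, "voxel_dataset"))
  if (length(w) != nrow(broad$data)) {
    stop("filter length ", length(w), " does not match ", nrow(broad$data),
         " voxels")
  }
  y <- drop(crossprod(w, center_rows(broad$data)))
  network_timeseries(y, frequency = frequency,
                     component_index = component_index,
                     sampling_rate = broad$sampling_rate,
                     subject_id = broad$subject_id,
                     condition = broad$condition)
}

#' Spatial activation pattern of a filter
#'
#' Forward projection of a spatial filter through the narrowband covariance:
#' `a = |S w|`, scaled by its maximum so the result lies in `[0, 1]` with
#' maximum exactly 1. Unlike the filter weights, the pattern is interpretable
#' as each voxel's contribution to the network.
#'
#' @param w spatial filter vector.
#' @param S narrowband covariance matrix.
#' @return Numeric pattern vector in `[0, 1]`.
#' @export
activation_pattern <- function(w, S) {
  if (length(w) != nrow(S)) stop("dimensions of w and S disagree")
  a <- abs(drop(S %*% w))
  m <- max(a)
  if (m == 0) stop("S %*% w is identically zero")
  a / m
}

#' Threshold an activation pattern for display
#'
#' Boolean mask of voxels whose activation strictly exceeds the pattern mean
#' plus one (sample) standard deviation.
#'
#' @param a pattern vector.
#' @return Logical vector, `TRUE` for displayed voxels.
#' @export
threshold_pattern_for_display <- function(a) {
  a > mean(a) + stats::sd(a)
}

# Internal: assemble a network_decomposition from eigenpairs of one frequency.
# Percent variance is always normalized over the FULL eigenvalue spectrum,
# then truncated to the retained components.
build_decomposition <- function(frequency, eigenvalues, W, S, n_keep, method,
                                regularization) {
  n_keep <- min(n_keep, length(eigenvalues))
  norm_full <- normalize_eigenvalues(eigenvalues)
  Wk <- W[, seq_len(n_keep), drop = FALSE]
  patterns <- vapply(seq_len(n_keep),
                     function(k) activation_pattern(Wk[, k], S),
                     numeric(nrow(Wk)))
  network_decomposition(frequency, eigenvalues[seq_len(n_keep)],
                        Wk, patterns, method = method,
                        regularization = regularization,
                        normalized_eigenvalues = norm_full[seq_len(n_keep)])
}

#' PCA variant of the per-frequency decomposition
#'
#' Eigendecomposition of the narrowband covariance alone (no broadband
#' reference), with the same downstream products as GED — normalized
#' eigenvalues, patterns `|S w|` scaled to max 1, time series `w' X_broad` —
#' so the two backends are directly comparable. Algebraically identical to
#' GED with `R = I`.
#'
#' @param narrow [narrowband_dataset()].
#' @param n_keep number of components to retain.
#' @return A [network_decomposition()] with `method = "PCA"`.
#' @export
pca_decomposition <- function(narrow, n_keep = 10) {
  stopifnot(inherits(narrow, "narrowband_dataset"))
  Xn <- center_rows(narrow$data)
  S <- tcrossprod(Xn)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- fix_signs(es$vectors, S)
  build_decomposition(narrow$center_frequency, es$values, W, S, n_keep,
                      method = "PCA", regularization = c(0, 0))
}

#' Scan the frequency grid and build a network landscape
#'
#' For each grid center: design the Gaussian kernel, narrowband filter the
#' broadband data, compute the covariance pair, solve the (generalized)
#' eigenproblem, and keep the top `n_keep` normalized eigenvalues, filters and
#' activation patterns. The broadband reference covariance and its Cholesky
#' factor are computed once per dataset and reused across frequencies.
#'
#' @param broad broadband [voxel_dataset()].
#' @param grid [frequency_grid()] (all centers below Nyquist).
#' @param method `"ged"` (narrowband vs broadband contrast) or `"pca"`
#'   (narrowband covariance alone).
#' @param n_keep components retained per frequency (default 10, the usual
#'   statistical focus).
#' @param gamma_S,gamma_R_fraction regularization, see [compute_covariances()].
#' @param verbose print one line per frequency.
#' @return An object of class `freqness_landscape`: list with `table` (tidy
#'   data frame: subject, condition, frequency, component, eigenvalue,
#'   eigenvalue_pct) and `decompositions` (one [network_decomposition()] per
#'   center, named by frequency).
#' @export
scan_frequencies <- function(broad, grid, method = c("ged", "pca"),
                             n_keep = 10, gamma_S = 1e-6,
                             gamma_R_fraction = 0.01, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(broad, "voxel_dataset"), inherits(grid, "frequency_grid"))
  nyq <- broad$sampling_rate / 2
  if (any(grid$centers >= nyq)) {
    stop("grid centers at or above Nyquist: ",
         paste(format(grid$centers[grid$centers >= nyq]), collapse = ", "))
  }
  n_keep <- min(n_keep, nrow(broad$data))
  T <- ncol(broad$data)
  Xb <- center_rows(broad$data)
  U <- NULL
  if (method == "ged") {
    R <- tcrossprod(Xb)
    R <- R + diag(gamma_R_fraction * sum(diag(R)) / nrow(R), nrow(R))
    U <- chol(R)
  }
  decomps <- vector("list", length(grid$centers))
  rows <- vector("list", length(grid$centers))
  for (i in seq_along(grid$centers)) {
    f <- grid$centers[i]
    kern <- design_gaussian_kernel(f, grid$fwhms[i], T, broad$sampling_rate)
    Xn <- center_rows(filter_matrix_rows(Xb, kern$gains))
    S <- tcrossprod(Xn)
    if (method == "ged") {
      S <- S + diag(gamma_S, nrow(S))
      sol <- solve_ged(list(S = S), chol_R = U)
      decomps[[i]] <- build_decomposition(f, sol$eigenvalues, sol$filters, S,
                                          n_keep, "GED",
                                          c(gamma_S, gamma_R_fraction))
    } else {
      es <- eigen((S + t(S)) / 2, symmetric = TRUE)
      W <- fix_signs(es$vectors, S)
      decomps[[i]] <- build_decomposition(f, es$values, W, S, n_keep, "PCA",
                                          c(0, 0))
    }
    d <- decomps[[i]]
    rows[[i]] <- data.frame(subject = broad$subject_id,
                            condition = broad$condition,
                            frequency = f,
                            component = seq_len(n_keep),
                            eigenvalue = d$eigenvalues[seq_len(n_keep)],
                            eigenvalue_pct = d$normalized_eigenvalues[seq_len(n_keep)])
    if (verbose) {
      message(sprintf("[%s/%s] %6.2f Hz: top eigenvalue %.3g%%",
                      broad$subject_id, broad$condition, f,
                      d$normalized_eigenvalues[1]))
    }
  }
  names(decomps) <- format(grid$centers)
  structure(list(table = do.call(rbind, rows), decompositions = decomps,
                 subject_id = broad$subject_id, condition = broad$condition,
                 grid = grid, method = toupper(method), n_keep = n_keep),
            class = "freqness_landscape")
}

#' @export
print.freqness_landscape <- function(x, ...) {
  peak <- x$table[x$table$component == 1, ]
  pk <- peak[which.max(peak$eigenvalue_pct), ]
  cat(sprintf("<freqness_landscape> %s, %d frequencies x %d components (%s/%s)\n",
              x$method, length(x$grid$centers), x$n_keep, x$subject_id,
              x$condition))
  cat(sprintf("  top component peaks at %g Hz with %.3g%% of variance\n",
              pk$frequency, pk$eigenvalue_pct))
  invisible(x)
}
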