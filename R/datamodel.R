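#' Construct a voxel dataset
#'
#' Container for one subject/condition recording: a voxels x time matrix of
#' source-space signal (arbitrary amplitude units) plus sampling metadata and
#' optional voxel coordinates.
#'
#' @param data numeric matrix, voxels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject label.
#' @param condition condition label (e.g. `"RS"`, `"PL"`).
#' @param coordinates optional `n_voxels x 3` matrix of MNI coordinates (mm).
#' @param grid_spacing_mm optional scalar lattice spacing in mm.
#' @return An object of class `voxel_dataset`.
#' @examples
#' d <- voxel_dataset(matrix(rnorm(4 * 600), 4, 600), sampling_rate = 250)
#' d
#' @export
voxel_dataset <- function(data, sampling_rate, subject_id = "s01",
                          condition = "RS", coordinates = NULL,
                          grid_spacing_mm = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop("non-finite value in voxel data at [", bad[1], ", ", bad[2], "]")
  }
  if (nrow(data) < 2) stop("need at least 2 voxels")
  if (length(sampling_rate) != 1 || !is.finite(sampling_rate) ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar (Hz)")
  }
  if (ncol(data) < 2 * sampling_rate) {
    stop("need at least 2 s of data (", 2 * sampling_rate, " samples)")
  }
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != nrow(data) || ncol(coordinates) != 3) {
      stop("coordinates must be an n_voxels x 3 matrix")
    }
    if (anyDuplicated(coordinates)) stop("coordinate rows must be unique")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         subject_id = as.character(subject_id),
         condition = as.character(condition),
         coordinates = coordinates, grid_spacing_mm = grid_spacing_mm),
    class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d voxels x %d samples (%.1f s at %g Hz), subject %s, condition %s\n",
              class(x)[1], nrow(x$data), ncol(x$data),
              ncol(x$data) / x$sampling_rate, x$sampling_rate,
              x$subject_id, x$condition))
  invisible(x)
}

#' @export
dim.voxel_dataset <- function(x) dim(x$data)

#' Construct a narrowband dataset
#'
#' Same shape and metadata as the parent broadband [voxel_dataset()], carrying
#' the narrowband-filtered signal and the filter parameters that produced it.
#' Usually created by [narrowband_filter()].
#'
#' @param parent the broadband `voxel_dataset`.
#' @param data filtered matrix, same dimensions as `parent$data`.
#' @param center_frequency filter center (Hz).
#' @param fwhm filter full width at half maximum gain (Hz).
#' @return An object of class `narrowband_dataset` (inherits `voxel_dataset`).
#' @export
narrowband_dataset <- function(parent, data, center_frequency, fwhm) {
  stopifnot(inherits(parent, "voxel_dataset"))
  if (!identical(dim(data), dim(parent$data))) {
    stop("narrowband data must match the parent dataset's dimensions")
  }
  out <- parent
  out$data <- data
  out$center_frequency <- center_frequency
  out$fwhm <- fwhm
  class(out) <- c("narrowband_dataset", "voxel_dataset")
  out
}

#' Construct a frequency grid
#'
#' Ordered scanning frequencies with one filter width per center. Most users
#' should call [build_frequency_grid()], which implements the default scanning
#' rule; this constructor only validates explicit centers/widths.
#'
#' @param centers strictly increasing vector of center frequencies (Hz).
#' @param fwhms filter widths (Hz), same length as `centers`.
#' @param stimulation_frequency optional stimulation frequency (Hz).
#' @param sampling_rate optional; if given, all centers must lie below Nyquist.
#' @return An object of class `frequency_grid`.
#' @export
frequency_grid <- function(centers, fwhms, stimulation_frequency = NULL,
                           sampling_rate = NULL) {
  centers <- as.numeric(centers)
  fwhms <- as.numeric(fwhms)
  if (length(centers) == 0) stop("empty frequency grid")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  if (any(centers <= 0)) stop("centers must all be positive")
  if (length(fwhms) != length(centers)) {
    stop("fwhms must have one entry per center")
  }
  if (any(fwhms <= 0)) stop("fwhms must all be positive")
  if (!is.null(sampling_rate)) {
    bad <- centers[centers >= sampling_rate / 2]
    if (length(bad)) {
      stop("centers at or above Nyquist (", sampling_rate / 2, " Hz): ",
           paste(format(bad), collapse = ", "))
    }
  }
  structure(list(centers = centers, fwhms = fwhms,
                 stimulation_frequency = stimulation_frequency),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d centers, %.4g-%.4g Hz", length(x$centers),
              min(x$centers), max(x$centers)))
  if (!is.null(x$stimulation_frequency)) {
    cat(sprintf(", stimulation %g Hz", x$stimulation_frequency))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.frequency_grid <- function(x) length(x$centers)

#' Construct a per-frequency network decomposition
#'
#' Holds, for one scanned frequency, the sorted (generalized) eigenvalues,
#' their percent-of-total-variance normalization, the spatial filters W
#' (columns, unit Euclidean norm), and the spatial activation patterns
#' (columns scaled to `[0, 1]` with maximum exactly 1).
#'
#' @param frequency scanned center frequency (Hz).
#' @param eigenvalues raw eigenvalues, sorted descending.
#' @param filters `n_voxels x n_components` matrix of spatial filters.
#' @param patterns `n_voxels x n_components` matrix of activation patterns.
#' @param method `"GED"` or `"PCA"`.
#' @param regularization numeric `c(gamma_S, gamma_R_fraction)`.
#' @param normalized_eigenvalues percent-of-total-variance values for the
#'   retained eigenvalues. When the stored eigenvalues are a truncated top-k
#'   set, pass percentages computed from the full spectrum; the default
#'   normalizes over the values given.
#' @return An object of class `network_decomposition`.
#' @export
network_decomposition <- function(frequency, eigenvalues, filters, patterns,
                                  method = c("GED", "PCA"),
                                  regularization = c(gamma_S = 1e-6,
                                                     gamma_R_fraction = 0.01),
                                  normalized_eigenvalues = NULL) {
  method <- match.arg(method)
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be sorted descending")
  if (ncol(filters) != length(eigenvalues) ||
      !identical(dim(filters), dim(patterns))) {
    stop("filters/patterns must have one column per eigenvalue")
  }
  if (is.null(normalized_eigenvalues)) {
    normalized_eigenvalues <- normalize_eigenvalues(eigenvalues)
  }
  if (length(normalized_eigenvalues) != length(eigenvalues)) {
    stop("normalized_eigenvalues must match eigenvalues in length")
  }
  structure(
    list(frequency = frequency, eigenvalues = eigenvalues,
         normalized_eigenvalues = normalized_eigenvalues,
         filters = filters, patterns = patterns, method = method,
         regularization = regularization),
    class = "network_decomposition")
}

#' @export
print.network_decomposition <- function(x, ...) {
  cat(sprintf("<network_decomposition> %s at %g Hz, %d components; top eigenvalue %.3g%% of variance\n",
              x$method, x$frequency, length(x$eigenvalues),
              x$normalized_eigenvalues[1]))
  invisible(x)
}

#' Construct a network activation time series
#'
#' The component time course obtained by applying a spatial filter to the
#' mean-centered broadband voxel data (`y = w' X`). Usually created by
#' [component_timeseries()].
#'
#' @param values numeric vector of samples.
#' @param frequency frequency of the component's decomposition (Hz).
#' @param component_index 1-based rank by explained variance.
#' @param sampling_rate sampling rate (Hz).
#' @param subject_id,condition labels inherited from the dataset.
#' @return An object of class `network_timeseries`.
#' @export
network_timeseries <- function(values, frequency, component_index,
                               sampling_rate, subject_id = "s01",
                               condition = "RS") {
  if (!all(is.finite(values))) stop("non-finite values in time series")
  structure(list(values = as.numeric(values), frequency = frequency,
                 component_index = as.integer(component_index),
                 sampling_rate = sampling_rate,
                 subject_id = subject_id, condition = condition),
            class = "network_timeseries")
}

#' @export
print.network_timeseries <- function(x, ...) {
  cat(sprintf("<network_timeseries> component %d at %g Hz, %d samples (%s/%s)\n",
              x$component_index, x$frequency, length(x$values),
              x$subject_id, x$condition))
  invisible(x)
}

# Internal: validate/assemble a tidy landscape table.
as_landscape_table <- function(df) {
  need <- c("subject", "condition", "frequency", "component", "eigenvalue_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landscape table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$subject, df$condition, df$frequency, df$component), ,
           drop = FALSE]
  rownames(df) <- NULL
  # eigenvalues must be non-increasing in component rank within each cell
  key <- interaction(df$subject, df$condition, df$frequency, drop = TRUE)
  ok <- tapply(df$eigenvalue_pct, key,
               function(v) all(diff(v) <= 1e-9 * max(abs(v), 1)))
  if (!all(unlist(ok))) {
    stop("eigenvalues must be non-increasing in component rank")
  }
  df
}
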