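# Randomization controls dissociating spatial from temporal structure.
#
# Both shuffles are applied after narrowband filtering (shuffling first would
# alter the filtering itself), and the same permutation(s) are applied to the
# broadband and narrowband matrices so that a single randomization — not two
# independent ones — is being tested.

copy_matrix <- function(m) m[seq_len(nrow(m)), , drop = FALSE]

#' Consistent voxel-label shuffle
#'
#' One random permutation of voxel indices applied identically to the rows of
#' the broadband and narrowband matrices (and to the coordinates, if present).
#' The time series themselves are untouched, so the eigenspectrum of the
#' downstream decomposition is preserved exactly while the spatial activation
#' patterns are permuted — i.e., spatially scrambled but spectrally intact.
#'
#' @param broad broadband [voxel_dataset()].
#' @param narrow optional matching [narrowband_dataset()].
#' @param seed RNG seed.
#' @return List with `broad`, `narrow` (or `NULL`) and the `permutation`
#'   applied.
#' @export
label_shuffle <- function(broad, narrow = NULL, seed) {
  stopifnot(inherits(broad, "voxel_dataset"))
  if (!is.null(narrow) && !identical(dim(narrow$data), dim(broad$data))) {
    stop("broad and narrow shapes differ")
  }
  set.seed(seed)
  perm <- sample(nrow(broad$data))
  out_b <- broad
  out_b$data <- broad$data[perm, , drop = FALSE]
  if (!is.null(out_b$coordinates)) {
    out_b$coordinates <- out_b$coordinates[perm, , drop = FALSE]
  }
  out_n <- NULL
  if (!is.null(narrow)) {
    out_n <- narrow
    out_n$data <- narrow$data[perm, , drop = FALSE]
    if (!is.null(out_n$coordinates)) {
      out_n$coordinates <- out_n$coordinates[perm, , drop = FALSE]
    }
  }
  list(broad = out_b, narrow = out_n, permutation = perm)
}

#' Point-wise voxel-label shuffle
#'
#' For every time sample, an independent random permutation of voxel indices
#' is applied to that column — the same permutation for the broadband and
#' narrowband matrices. This destroys the cross-voxel covariance structure and
#' the temporal structure of every voxel's series, collapsing the top
#' normalized eigenvalue of the downstream decomposition toward its chance
#' floor (see [ged_chance_level()]).
#'
#' @inheritParams label_shuffle
#' @return List with `broad` and `narrow` (or `NULL`).
#' @export
pointwise_label_shuffle <- function(broad, narrow = NULL, seed) {
  stopifnot(inherits(broad, "voxel_dataset"))
  if (!is.null(narrow) && !identical(dim(narrow$data), dim(broad$data))) {
    stop("broad and narrow shapes differ")
  }
  out_b <- broad
  Xb <- copy_matrix(broad$data)
  set.seed(seed)
  shuffle_columns_inplace(Xb)
  out_b$data <- Xb
  out_n <- NULL
  if (!is.null(narrow)) {
    out_n <- narrow
    Xn <- copy_matrix(narrow$data)
    set.seed(seed)                      # same RNG stream -> same permutations
    shuffle_columns_inplace(Xn)
    out_n$data <- Xn
  }
  list(broad = out_b, narrow = out_n)
}
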