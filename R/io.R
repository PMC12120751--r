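# Plain-text container formats. Matrices travel as TSV with `#key<TAB>value`
# metadata header lines; landscapes as tidy TSV with a header row. Numeric
# payloads are written with 17 significant digits so float64 round-trips are
# lossless.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a voxel dataset to TSV
#'
#' Tab-delimited matrix (voxels in rows, no header row) preceded by
#' `#key<TAB>value` metadata lines (`sampling_rate`, `subject_id`,
#' `condition`, optionally `grid_spacing_mm`) and, when coordinates are
#' present, `#coord` lines with one MNI-mm triplet per voxel.
#'
#' @param dataset a [voxel_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voxel_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#sampling_rate\t", fmt_full(dataset$sampling_rate)),
               paste0("#subject_id\t", dataset$subject_id),
               paste0("#condition\t", dataset$condition)), con)
  if (!is.null(dataset$grid_spacing_mm)) {
    writeLines(paste0("#grid_spacing_mm\t", fmt_full(dataset$grid_spacing_mm)),
               con)
  }
  if (!is.null(dataset$coordinates)) {
    writeLines(paste0("#coord\t",
                      apply(dataset$coordinates, 1, function(r)
                        paste(fmt_full(r), collapse = "\t"))), con)
  }
  writeLines(apply(dataset$data, 1, function(r)
    paste(fmt_full(r), collapse = "\t")), con)
  invisible(path)
}

#' Read a voxel dataset from TSV
#'
#' Counterpart of [write_voxel_dataset()]. Plain matrices without metadata
#' header lines are accepted if `sampling_rate` is supplied.
#'
#' @param path input file path.
#' @param sampling_rate sampling rate (Hz); required when the file carries no
#'   `#sampling_rate` header.
#' @return A [voxel_dataset()].
#' @export
read_voxel_dataset <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- strsplit(sub("^#", "", lines[is_meta]), "\t")
  keys <- vapply(meta, `[[`, character(1), 1)
  subject_id <- "s01"; condition <- "RS"; grid_spacing <- NULL; coords <- NULL
  if ("sampling_rate" %in% keys) {
    sampling_rate <- as.numeric(meta[[which(keys == "sampling_rate")[1]]][2])
  }
  if (is.null(sampling_rate) || is.na(sampling_rate)) {
    stop("sampling rate missing: not in file metadata and not supplied")
  }
  if ("subject_id" %in% keys) subject_id <- meta[[which(keys == "subject_id")[1]]][2]
  if ("condition" %in% keys) condition <- meta[[which(keys == "condition")[1]]][2]
  if ("grid_spacing_mm" %in% keys) {
    grid_spacing <- as.numeric(meta[[which(keys == "grid_spacing_mm")[1]]][2])
  }
  if (any(keys == "coord")) {
    coords <- do.call(rbind, lapply(meta[keys == "coord"], function(m)
      as.numeric(m[-1])))
  }
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  M <- suppressWarnings(matrix(as.numeric(as.matrix(dt)), nrow(dt), ncol(dt)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("non-numeric or non-finite cell at matrix position [", bad[1], ", ",
         bad[2], "]")
  }
  voxel_dataset(M, sampling_rate = sampling_rate, subject_id = subject_id,
                condition = condition, coordinates = coords,
                grid_spacing_mm = grid_spacing)
}

#' Write a landscape table to tidy TSV
#'
#' Columns `subject`, `condition`, `frequency_hz`, `component`,
#' `eigenvalue_pct` (full float64 precision). The component-rank ordering
#' invariant (non-increasing eigenvalue within each subject/condition/
#' frequency) is enforced on write and on read.
#'
#' @param landscape a [scan_frequencies()] result, a tidy landscape data
#'   frame, or a list of either.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  tab <- stack_landscape(landscape)
  if (nrow(tab) == 0) stop("refusing to write an empty landscape")
  out <- data.frame(subject = tab$subject, condition = tab$condition,
                    frequency_hz = fmt_full(tab$frequency),
                    component = tab$component,
                    eigenvalue_pct = fmt_full(tab$eigenvalue_pct))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a landscape table from tidy TSV
#'
#' @param path input file path.
#' @return Tidy landscape data frame (columns `subject`, `condition`,
#'   `frequency`, `component`, `eigenvalue_pct`).
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  names(dt)[names(dt) == "frequency_hz"] <- "frequency"
  as_landscape_table(dt)
}

#' Export a spatial activation pattern as a NIfTI volume
#'
#' Places each pattern value at the lattice voxel nearest its MNI coordinate
#' on an axis-aligned grid with uniform spacing; off-grid voxels are zero. The
#' affine maps voxel indices back to the given MNI mm coordinates.
#'
#' @param pattern numeric pattern vector (one value per voxel).
#' @param coordinates `n_voxels x 3` MNI mm coordinates.
#' @param grid_spacing_mm lattice spacing (mm).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_pattern_volume <- function(pattern, coordinates, grid_spacing_mm,
                                  path) {
  if (is.null(coordinates)) {
    stop("unsupported operation: dataset has no voxel coordinates")
  }
  coordinates <- as.matrix(coordinates)
  stopifnot(length(pattern) == nrow(coordinates), ncol(coordinates) == 3)
  origin <- apply(coordinates, 2, min)
  ijk <- sweep(coordinates, 2, origin) / grid_spacing_mm
  if (max(abs(ijk - round(ijk))) > 1e-6) {
    stop("grid_spacing_mm does not divide the coordinate lattice")
  }
  ijk <- round(ijk) + 1
  dims <- apply(ijk, 2, max)
  vol <- array(0, dim = dims)
  vol[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- pattern
  # qform maps 0-based voxel indices to world mm, so voxel (0,0,0) sits at
  # the coordinate-lattice origin
  affine <- diag(c(rep(grid_spacing_mm, 3), 1))
  affine[1:3, 4] <- origin
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Sample a NIfTI pattern volume at MNI coordinates
#'
#' Inverse of [export_pattern_volume()]: uses the stored affine to map each
#' coordinate to its voxel index and returns the stored value.
#'
#' @param path NIfTI file path.
#' @param coordinates `n x 3` MNI mm coordinates.
#' @return Numeric vector of sampled values.
#' @export
sample_pattern_volume <- function(path, coordinates) {
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img)
  inv <- solve(affine)
  xyz1 <- cbind(as.matrix(coordinates), 1)
  ijk <- round(xyz1 %*% t(inv))[, 1:3, drop = FALSE] + 1  # 0-based -> R index
  arr <- as.array(img)
  arr[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
}
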