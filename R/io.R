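#' Write a BOLD series as NIfTI-1
#'
#' Voxel size and TR are recorded in the header pixdims (mm / s).
#'
#' @param series A [bold_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 4D NIfTI-1 file as a BOLD series
#'
#' Voxel size and TR are taken from the header pixdims; scaling slopes
#' and byte order are honored by the reader.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param space_tag Label to attach to the series.
#' @return A [bold_series()].
#' @export
read_bold_nifti <- function(path, space_tag = "phantom") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("%s: expected a 4D series, got %dD", path, length(d)),
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  bold_series(array(as.numeric(img), d), tr = pd[4], voxel_size = pd[1:3],
              space_tag = space_tag)
}

#' Write a 3D map or mask as NIfTI-1
#'
#' @param data 3D array (logical masks are written as uint8).
#' @param path Output path.
#' @param voxel_size Voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(data, path, voxel_size = c(1, 1, 1)) {
  is_mask <- is.logical(data)
  img <- RNifti::asNifti(array(if (is_mask) as.integer(data) else data,
                               dim(data)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Read a 3D NIfTI-1 map
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as_mask If `TRUE`, return a logical array (non-zero voxels).
#' @return List with `data` (3D array) and `voxel_size`.
#' @export
read_map_nifti <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("%s: expected a 3D map, got %dD", path, length(d)),
         call. = FALSE)
  data <- array(as.numeric(img), d)
  if (as_mask) data <- array(data != 0, d)
  list(data = data, voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a motion trace as TSV
#'
#' Writes a 6-column parameter file (tx, ty, tz in mm; rx, ry, rz in
#' radians) and, alongside it, a 12-column affine file (the first three
#' rows of each 4x4 transform, row-major) at `<path stem>_affines.tsv`.
#'
#' @param trace A [motion_trace()].
#' @param path Output TSV path for the parameters.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(trace, path) {
  write.table(trace$params, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  aff <- t(apply(trace$affines, 3, function(a) as.vector(t(a[1:3, ]))))
  colnames(aff) <- paste0("m", rep(1:3, each = 4), rep(1:4, 3))
  write.table(aff, affine_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
affine_path <- function(path) sub("(\\.tsv)?$", "_affines.tsv",
                                  sub("\\.tsv$", "", path))

#' Read a motion trace from TSV
#'
#' Accepts the pair written by [write_motion_tsv()]; if the affine file is
#' absent, affines are reconstructed from the 6 parameters (rotation about
#' the volume-center origin). Plain whitespace-separated 6-column files in
#' the same column order are also accepted.
#'
#' @param path Parameter TSV path.
#' @return A [motion_trace()].
#' @export
read_motion_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  params <- as.matrix(read.delim(path, sep = "", header = TRUE))
  ap <- affine_path(path)
  nt <- nrow(params)
  if (file.exists(ap)) {
    aff12 <- as.matrix(read.delim(ap, sep = "", header = TRUE))
    affines <- array(0, c(4, 4, nt))
    for (v in seq_len(nt)) {
      affines[1:3, , v] <- matrix(aff12[v, ], 3, 4, byrow = TRUE)
      affines[4, , v] <- c(0, 0, 0, 1)
    }
  } else {
    affines <- array(0, c(4, 4, nt))
    for (v in seq_len(nt)) affines[, , v] <- rigid_affine(params[v, ])
  }
  motion_trace(params, affines)
}

#' Write / read a cohort table as TSV
#'
#' Tab-separated, UTF-8, `.` decimal, `NA` for missing values. Mandatory
#' columns: `subject_id`, `group`, `age`, `wmh_count`; any further columns
#' are scores.
#'
#' @param cohort Cohort data frame.
#' @param path TSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cohort <- read.delim(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("subject_id", "group", "age", "wmh_count")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("cohort table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  cohort
}

#' Write a cluster table as TSV
#'
#' @param clusters A `cluster_table`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  write.table(as.data.frame(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
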