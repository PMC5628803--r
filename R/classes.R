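#' BOLD series container
#'
#' A 4D BOLD acquisition on a common voxel grid: the raw array plus the
#' timing and geometry needed downstream (repetition time, voxel size, and
#' a tag naming the common space all subjects share).
#'
#' @param data 4D numeric array (x, y, z, t), arbitrary signal units.
#' @param tr Repetition time in seconds.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param space_tag Label of the common grid the series lives on.
#' @param validate Scan the array for non-finite values (default TRUE;
#'   internal callers that construct the data may skip it).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, voxel_size, space_tag = "phantom",
                        validate = TRUE) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array", call. = FALSE)
  if (dim(data)[4] < 3L) stop("series needs at least 3 volumes", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive mm lengths", call. = FALSE)
  if (validate && !all(is.finite(data)))
    stop("series contains non-finite values", call. = FALSE)
  structure(list(data = data, tr = tr, voxel_size = voxel_size,
                 space_tag = space_tag), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d grid, %d volumes, TR %g s, voxel %s mm, space '%s'\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(signif(x$voxel_size, 3), collapse = "x"), x$space_tag))
  invisible(x)
}

#' Number of volumes in a BOLD series
#' @param series A `bold_series`.
#' @return Integer count of volumes.
#' @export
n_volumes <- function(series) dim(series$data)[4]

#' ALFF map container
#'
#' A 3D map of band-limited fluctuation amplitude, zero outside its mask.
#' After normalization the in-mask mean is 1 and values are unitless.
#'
#' @param data 3D numeric array.
#' @param band Length-2 numeric, the frequency band in Hz.
#' @param mask Logical 3D array used for computation/normalization.
#' @param normalized Logical flag: has the map been divided by its in-mask mean?
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @return An object of class `alff_map`.
#' @export
alff_map <- function(data, band, mask, normalized = FALSE,
                     voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  mask <- check_mask(mask, dim(data))
  structure(list(data = data, band = as.numeric(band), mask = mask,
                 normalized = isTRUE(normalized),
                 voxel_size = as.numeric(voxel_size)),
            class = "alff_map")
}

#' @export
print.alff_map <- function(x, ...) {
  cat(sprintf("<alff_map> %s grid, band %.3f-%.3f Hz, %s, %d mask voxels\n",
              paste(dim(x$data), collapse = "x"), x$band[1], x$band[2],
              if (x$normalized) "normalized (in-mask mean 1)" else "unnormalized",
              sum(x$mask)))
  invisible(x)
}

#' Voxelwise statistic map container
#'
#' @param data 3D array of test statistics.
#' @param df Degrees of freedom: length 1 for t, length 2 for F.
#' @param stat_kind `"t"` or `"F"`.
#' @param mask Logical analysis mask.
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(data, df, stat_kind = c("t", "F"), mask,
                     voxel_size = c(1, 1, 1)) {
  stat_kind <- match.arg(stat_kind)
  if (stat_kind == "t" && length(df) != 1L) stop("t map needs scalar df", call. = FALSE)
  if (stat_kind == "F" && length(df) != 2L) stop("F map needs df pair", call. = FALSE)
  mask <- check_mask(mask, dim(data))
  structure(list(data = data, df = as.numeric(df), stat_kind = stat_kind,
                 mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s statistics, df %s, %d mask voxels\n",
              x$stat_kind, paste(x$df, collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' Motion trace container
#'
#' Per-volume rigid-body realignment parameters (3 translations in mm,
#' 3 rotations in radians) together with the equivalent 4x4 rigid affine
#' mapping each volume to the reference. Rotations are taken about the
#' volume center, which is the coordinate origin of the phantom space.
#'
#' @param params T x 6 matrix, columns tx, ty, tz (mm), rx, ry, rz (radians).
#' @param affines 4 x 4 x T array of rigid transforms.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params, affines) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("params must have 6 columns", call. = FALSE)
  if (nrow(params) < 1L) stop("empty motion trace", call. = FALSE)
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!identical(dim(affines)[1:2], c(4L, 4L)) || dim(affines)[3] != nrow(params))
    stop("affines must be 4x4xT matching params rows", call. = FALSE)
  for (v in seq_len(dim(affines)[3])) {
    R <- affines[1:3, 1:3, v]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop("affines must be rigid (orthonormal rotation, det +1)", call. = FALSE)
  }
  structure(list(params = params, affines = affines), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes, max |trans| %.3g mm, max |rot| %.3g rad\n",
              nrow(x$params), max(abs(x$params[, 1:3])), max(abs(x$params[, 4:6]))))
  invisible(x)
}

# Rigid 4x4 affine from 6 parameters, rotation about the origin.
#' @noRd
rigid_affine <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- diag(4)
  A[1:3, 1:3] <- Rx %*% Ry %*% Rz
  A[1:3, 4] <- p[1:3]
  A
}
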