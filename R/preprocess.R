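#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a series (signal equilibration
#' period at the start of an acquisition). Timing metadata is unchanged.
#'
#' @param series A [bold_series()].
#' @param n_discard Number of leading volumes to drop (default 2).
#' @return The shortened [bold_series()].
#' @export
discard_initial_volumes <- function(series, n_discard = 2) {
  nt <- n_volumes(series)
  if (n_discard < 0 || n_discard >= nt)
    stop(sprintf("n_discard = %d must be in [0, %d)", n_discard, nt),
         call. = FALSE)
  if (n_discard == 0) return(series)
  series$data <- series$data[, , , -seq_len(n_discard), drop = FALSE]
  series
}

#' Slice-timing correction
#'
#' Shifts each slice's time series to a common reference acquisition time
#' within the TR by linear temporal interpolation. Slices are assumed
#' acquired back-to-back in the order given by `slice_order` (default
#' sequential ascending); the reference time is `ref_fraction * TR`
#' (default 0.5, the temporal midpoint of the volume). The first and last
#' samples are clamped.
#'
#' @param series A [bold_series()].
#' @param slice_axis Spatial axis along which slices were acquired (1-3).
#' @param slice_order Permutation of slice indices giving acquisition order.
#' @param ref_fraction Reference time as a fraction of TR in `[0, 1]`.
#' @return The corrected [bold_series()].
#' @export
slice_timing_correct <- function(series, slice_axis = 3,
                                 slice_order = NULL, ref_fraction = 0.5) {
  d <- dim(series$data)
  nsl <- d[slice_axis]
  nt <- d[4]
  if (is.null(slice_order)) slice_order <- seq_len(nsl)
  if (!identical(sort(as.integer(slice_order)), seq_len(nsl)))
    stop("slice_order must be a permutation of slice indices", call. = FALSE)
  if (ref_fraction < 0 || ref_fraction > 1)
    stop("ref_fraction must be in [0, 1]", call. = FALSE)

  # acquisition time of slice s within the TR
  slice_time <- (match(seq_len(nsl), slice_order) - 1) / nsl * series$tr
  ref_time <- ref_fraction * series$tr

  perm <- c(setdiff(1:3, slice_axis), slice_axis, 4)
  arr <- aperm(series$data, perm)
  da <- dim(arr)
  nsp <- da[1] * da[2]

  for (s in seq_len(nsl)) {
    delta <- (ref_time - slice_time[s]) / series$tr  # shift in volume units
    if (abs(delta) < 1e-12) next
    pos <- pmin(pmax(seq_len(nt) + delta, 1), nt)
    i0 <- pmin(floor(pos), nt - 1)
    w <- pos - i0
    slab <- matrix(arr[, , s, ], nsp, nt)
    arr[, , s, ] <- slab[, i0, drop = FALSE] * rep(1 - w, each = nsp) +
      slab[, i0 + 1, drop = FALSE] * rep(w, each = nsp)
  }
  series$data <- aperm(arr, order(c(perm[1:3], 4)))
  series
}

#' RMS displacement between two rigid transforms
#'
#' Closed-form root-mean-square displacement of points uniformly
#' distributed in a sphere of radius `radius` centered at `center`, under
#' the relative transform between two rigid affines: with the relative
#' transform written as rotation `R` and translation `t`,
#' `rms^2 = (radius^2 / 5) * ||R - I||_F^2 + ||t + (R - I) c||^2`.
#' Symmetric in its two arguments and independent of radius for pure
#' translations.
#'
#' @param affine_a,affine_b 4x4 rigid affines.
#' @param radius Sphere radius in mm (default 80, a head-sized sphere).
#' @param center Sphere center in mm (default the origin, i.e. the volume
#'   center in phantom coordinates).
#' @return RMS displacement in mm.
#' @export
motion_rms <- function(affine_a, affine_b = diag(4), radius = 80,
                       center = c(0, 0, 0)) {
  for (a in list(affine_a, affine_b)) {
    if (!identical(dim(a), c(4L, 4L)) || abs(det(a)) < 1e-12)
      stop("affines must be invertible 4x4 matrices", call. = FALSE)
  }
  m <- solve(affine_b) %*% affine_a
  A <- m[1:3, 1:3] - diag(3)
  t <- m[1:3, 4] + A %*% center
  sqrt(radius^2 / 5 * sum(A^2) + sum(t^2))
}

#' Motion quality-control filter
#'
#' Excludes subjects whose maximum volume-to-reference RMS displacement
#' exceeds `threshold` (default 1.5 mm).
#'
#' @param traces Named list of [motion_trace()] objects (names = subject ids).
#' @param threshold RMS exclusion threshold in mm.
#' @param radius,center Passed to [motion_rms()].
#' @return List with `kept`, `excluded` (character vectors of ids) and
#'   `max_rms` (named numeric, per-subject maximum RMS in mm).
#' @export
qc_filter <- function(traces, threshold = 1.5, radius = 80,
                      center = c(0, 0, 0)) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (!length(traces)) stop("no motion traces supplied", call. = FALSE)
  ids <- names(traces) %||% as.character(seq_along(traces))
  max_rms <- vapply(traces, function(tr) {
    nv <- dim(tr$affines)[3]
    if (nv < 1) stop("empty motion trace", call. = FALSE)
    max(vapply(seq_len(nv), function(v)
      motion_rms(tr$affines[, , v], diag(4), radius, center), numeric(1)))
  }, numeric(1))
  names(max_rms) <- ids
  list(kept = ids[max_rms <= threshold], excluded = ids[max_rms > threshold],
       max_rms = max_rms)
}

# 1D Gaussian convolution matrix with symmetric (reflective) boundary.
#' @noRd
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-8) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma_vox))
  w <- dnorm(seq(-radius, radius), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in seq(-radius, radius)) {
      p <- i + o
      while (p < 1 || p > n) p <- if (p < 1) 1 - p else 2 * n + 1 - p
      K[i, p] <- K[i, p] + w[o + radius + 1]
    }
  }
  K
}

# Apply an axis-wise linear operator to a 3D or 4D array.
#' @noRd
apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, da[1], prod(da[-1]))
  dim(a) <- da
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable Gaussian kernel of the given
#' full-width-at-half-maximum in mm, isotropic in physical space (the
#' per-axis kernel accounts for anisotropic voxel sizes). Symmetric
#' (reflective) boundary handling, so a constant image stays constant.
#' `fwhm = 0` is the identity.
#'
#' @param series A [bold_series()] or a 3D array with `voxel_size` supplied.
#' @param fwhm Kernel FWHM in mm (>= 0).
#' @param voxel_size Voxel size in mm, taken from the series if omitted.
#' @return The smoothed object (same class as input).
#' @export
smooth_gaussian <- function(series, fwhm = 8, voxel_size = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  is_series <- inherits(series, "bold_series")
  vs <- voxel_size %||% if (is_series) series$voxel_size else
    stop("voxel_size required for bare arrays", call. = FALSE)
  if (fwhm == 0) return(series)
  arr <- if (is_series) series$data else series
  d <- dim(arr)
  for (axis in 1:3) {
    K <- gauss_conv_matrix(d[axis], fwhm_to_sigma(fwhm) / vs[axis])
    arr <- apply_axis(arr, K, axis)
  }
  if (is_series) { series$data <- arr; series } else arr
}

#' Grand-mean intensity normalization
#'
#' Rescales a series by one global factor so the grand mean over in-mask
#' voxels and all volumes equals `target` (default 10000).
#'
#' @param series A [bold_series()].
#' @param brain_mask Logical 3D mask.
#' @param target Target grand mean, signal units.
#' @return The rescaled [bold_series()].
#' @export
normalize_intensity <- function(series, brain_mask, target = 10000) {
  d <- dim(series$data)
  brain_mask <- check_mask(brain_mask, d[1:3], "brain_mask")
  if (!any(brain_mask)) stop("brain_mask is empty", call. = FALSE)
  sm <- series_matrix(series, brain_mask)
  gm <- mean(sm$y)
  if (gm <= 0) stop("in-mask grand mean must be > 0", call. = FALSE)
  series$data <- series$data * (target / gm)
  series
}

#' CompCor noise components
#'
#' Pools the voxel time series of the noise regions-of-non-interest,
#' removes each voxel's mean and linear trend, scales each voxel to unit
#' variance, and returns the top `n_components` left singular vectors as
#' component time series (unit norm, mutually orthogonal, ordered by
#' singular value). The sign of each component is fixed so that its
#' largest-magnitude element is positive.
#'
#' @param series A [bold_series()] (use the unsmoothed series so the
#'   noise compartments are not contaminated by smoothed gray matter).
#' @param noise_masks List of logical 3D masks (white matter, CSF,
#'   out-of-brain), pooled.
#' @param n_components Number of components to return (default 5).
#' @return T x `n_components` matrix with columns `compcor1..n`.
#' @export
compcor_components <- function(series, noise_masks, n_components = 5) {
  d <- dim(series$data)
  pooled <- Reduce(`|`, lapply(noise_masks, check_mask, d[1:3], "noise mask"))
  sm <- series_matrix(series, pooled)
  y <- detrend_linear(sm$y)
  sds <- sqrt(colSums(y^2) / (nrow(y) - 1))
  ok <- sds > 1e-10 * max(sds, 1e-300)
  if (sum(ok) < n_components)
    stop(sprintf("only %d noise voxels with non-zero variance; need >= %d",
                 sum(ok), n_components), call. = FALSE)
  y <- sweep(y[, ok, drop = FALSE], 2, sds[ok], "/")
  u <- svd(y, nu = n_components, nv = 0)$u
  for (j in seq_len(ncol(u))) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("compcor", seq_len(n_components))
  u
}

#' Assemble the nuisance regression design
#'
#' Columns are the 6 rigid-body motion parameters, their temporal
#' derivatives computed by backward differences (first row zero), and the
#' CompCor components - 17 regressors with the default 5 components.
#'
#' @param trace A [motion_trace()].
#' @param components T x k matrix of CompCor components.
#' @return An object of class `nuisance_design` with elements `matrix`
#'   (T x 17) and `labels`.
#' @export
build_nuisance_design <- function(trace, components) {
  motion <- trace$params
  components <- as.matrix(components)
  if (nrow(components) != nrow(motion))
    stop(sprintf("components rows (%d) must match motion rows (%d)",
                 nrow(components), nrow(motion)), call. = FALSE)
  deriv <- rbind(0, diff(motion))
  labels <- c(colnames(motion), paste0("d", colnames(motion)),
              colnames(components) %||% paste0("compcor", seq_len(ncol(components))))
  m <- cbind(motion, deriv, components)
  colnames(m) <- labels
  structure(list(matrix = m, labels = labels), class = "nuisance_design")
}

#' @export
print.nuisance_design <- function(x, ...) {
  cat(sprintf("<nuisance_design> %d volumes x %d regressors: %s\n",
              nrow(x$matrix), ncol(x$matrix), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Nuisance regression
#'
#' Per in-mask voxel, removes the ordinary-least-squares fit of the time
#' series on the nuisance design (an intercept is added internally and not
#' counted among the regressors). Each voxel's mean is restored after
#' regression so downstream ALFF normalization remains well defined;
#' out-of-mask voxels are zeroed. Degenerate design columns (all-constant
#' or duplicated) are pruned with a warning - a motionless phantom is a
#' legitimate input.
#'
#' @param series A [bold_series()].
#' @param design A `nuisance_design` from [build_nuisance_design()].
#' @param brain_mask Logical 3D mask.
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, design, brain_mask) {
  d <- dim(series$data)
  brain_mask <- check_mask(brain_mask, d[1:3], "brain_mask")
  X <- design$matrix
  if (nrow(X) != d[4])
    stop("design rows must match volume count", call. = FALSE)

  keep <- apply(X, 2, function(col) diff(range(col)) > 1e-12)
  dup <- duplicated(t(X))
  drop_cols <- !keep | dup
  if (any(drop_cols)) {
    warning(sprintf("pruned %d degenerate design column(s): %s",
                    sum(drop_cols),
                    paste(colnames(X)[drop_cols], collapse = ", ")))
    X <- X[, !drop_cols, drop = FALSE]
  }
  Xi <- cbind(`(intercept)` = 1, X)
  if (d[4] <= ncol(Xi))
    stop("too few volumes for the nuisance design", call. = FALSE)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[seq(qx$rank + 1, ncol(Xi))]]
    stop(sprintf("nuisance design is rank deficient after pruning; offending columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  sm <- series_matrix(series, brain_mask)
  res <- qr.resid(qx, sm$y)
  res <- sweep(res, 2, colMeans(sm$y), "+")
  out <- matrix(0, prod(d[1:3]), d[4])
  out[sm$idx, ] <- t(res)
  series$data <- array(out, d)
  series
}
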