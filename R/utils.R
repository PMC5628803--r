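# Internal helpers shared across stages.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert FWHM (mm) to Gaussian sigma.
#' @noRd
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Extract the in-mask time-by-voxel matrix of a bold_series.
#' @noRd
series_matrix <- function(series, mask) {
  d <- dim(series$data)
  nt <- d[4]
  idx <- which(mask)
  m <- matrix(series$data, prod(d[1:3]), nt)[idx, , drop = FALSE]
  list(y = t(m), idx = idx)
}

# Remove per-column mean and linear trend from a T x V matrix.
#
# With `protect_bins` given (one-sided Fourier bin indices), the slope is
# estimated with those sin/cos modes partialled out of the time regressor,
# and the raw fitted line is then removed. A pure ramp is still removed
# exactly (its slope estimate is unchanged), while a sinusoid on a
# protected bin is untouched: detrending cannot bias protected-band
# amplitudes.
#' @noRd
detrend_linear <- function(y, protect_bins = NULL) {
  nt <- nrow(y)
  tc <- seq_len(nt) - (nt + 1) / 2
  ct <- tc
  if (length(protect_bins)) {
    tt <- seq_len(nt) - 1
    for (k in protect_bins) {
      for (ph in list(sin, cos)) {
        s <- ph(2 * pi * k * tt / nt)
        ns <- sum(s^2)
        if (ns > 1e-12) ct <- ct - sum(s * tc) / ns * s
      }
    }
  }
  slope <- crossprod(ct, y)[1, ] / sum(ct * tc)
  y <- sweep(y, 2, colMeans(y), "-")
  y - outer(tc, slope)
}

# Draw a derived RNG seed (31-bit) from the current R stream.
#' @noRd
derive_seed <- function(n = 1L) sample.int(.Machine$integer.max, n)

# Validate a logical 3D mask against a grid.
#' @noRd
check_mask <- function(mask, dims, what = "mask") {
  if (!is.logical(mask)) mask <- array(mask != 0, dim = dim(mask))
  if (!identical(dim(mask), as.integer(dims)))
    stop(sprintf("%s dimensions %s do not match grid %s", what,
                 paste(dim(mask), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  mask
}

# 1-based voxel (i,j,k) from column-major linear indices.
#' @noRd
vox_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  k <- idx0 %/% (dims[1] * dims[2])
  r <- idx0 %% (dims[1] * dims[2])
  cbind(i = r %% dims[1] + 1L, j = r %/% dims[1] + 1L, k = k + 1L)
}
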