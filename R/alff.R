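# Frequency of each one-sided Fourier bin k = 1..floor(T/2), in Hz.
#' @noRd
bin_freqs <- function(nt, tr) seq_len(floor(nt / 2)) / (nt * tr)

# Indices (k) of one-sided bins inside [f_lo, f_hi], inclusive.
#' @noRd
band_bins <- function(nt, tr, f_lo, f_hi) {
  fk <- bin_freqs(nt, tr)
  which(fk >= f_lo & fk <= f_hi)
}

#' Ideal band-pass filter
#'
#' Frequency-domain band-pass: Fourier coefficients at frequencies outside
#' `[f_lo, f_hi]` (including DC) are zeroed and the series inverse
#' transformed. Linear and idempotent; with `f_lo = 0` the DC component is
#' still removed.
#'
#' @param series A [bold_series()].
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must not exceed the Nyquist
#'   frequency `1/(2 TR)`.
#' @return The filtered [bold_series()] (zero-mean in time).
#' @export
bandpass_filter <- function(series, f_lo = 0.008, f_hi = 0.09) {
  nt <- n_volumes(series)
  nyq <- 1 / (2 * series$tr)
  if (f_lo < 0 || f_lo >= f_hi)
    stop("need 0 <= f_lo < f_hi", call. = FALSE)
  if (f_hi > nyq + 1e-12)
    stop(sprintf("f_hi = %g Hz exceeds Nyquist = %g Hz (TR = %g s)",
                 f_hi, nyq, series$tr), call. = FALSE)
  d <- dim(series$data)
  # two-sided frequency of FFT index k (0-based): min(k, T-k)/(T*tr)
  k <- 0:(nt - 1)
  f2 <- pmin(k, nt - k) / (nt * series$tr)
  keep <- f2 >= f_lo & f2 <= f_hi & k != 0
  y <- matrix(series$data, prod(d[1:3]), nt)
  co <- mvfft(t(y))
  co[!keep, ] <- 0
  y <- Re(mvfft(co, inverse = TRUE)) / nt
  series$data <- array(t(y), d)
  series
}

#' Compute an (unnormalized) ALFF map
#'
#' Per in-mask voxel: remove mean and linear trend, take the discrete
#' Fourier transform, convert to the one-sided amplitude spectrum
#' `a_k = 2 |X_k| / T` at frequencies `f_k = k / (T TR)` (the factor is 1
#' at the Nyquist bin of an even-length series), and average `a_k` over
#' the bins with `f_lo <= f_k <= f_hi`. With this scaling a pure in-band
#' sinusoid of amplitude A planted on an exact Fourier bin contributes
#' `A / n_bins` to the voxel's ALFF - exactly: the trend slope is
#' estimated with the in-band Fourier modes partialled out of the time
#' regressor, so detrending removes a pure drift ramp completely (its
#' in-band leakage included) yet cannot bias in-band amplitudes.
#' Out-of-mask voxels are zero.
#'
#' @param series A [bold_series()] (preprocessed).
#' @param f_lo,f_hi Band edges in Hz (defaults 0.008 and 0.09).
#' @param brain_mask Logical 3D mask.
#' @return An unnormalized [alff_map()].
#' @export
compute_alff <- function(series, f_lo = 0.008, f_hi = 0.09, brain_mask) {
  nt <- n_volumes(series)
  if (nt < 8) stop("need at least 8 volumes", call. = FALSE)
  nyq <- 1 / (2 * series$tr)
  if (f_lo < 0 || f_lo >= f_hi || f_hi > nyq + 1e-12)
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz", f_lo, f_hi, nyq),
         call. = FALSE)
  d <- dim(series$data)
  brain_mask <- check_mask(brain_mask, d[1:3], "brain_mask")
  bins <- band_bins(nt, series$tr, f_lo, f_hi)
  if (!length(bins))
    stop(sprintf(
      "no Fourier bin falls inside [%g, %g] Hz with T = %d, TR = %g s",
      f_lo, f_hi, nt, series$tr), call. = FALSE)

  sm <- series_matrix(series, brain_mask)
  y <- detrend_linear(sm$y, protect_bins = bins)
  amp <- 2 * Mod(mvfft(y)) / nt
  if (nt %% 2 == 0) amp[nt / 2 + 1, ] <- amp[nt / 2 + 1, ] / 2
  vals <- colMeans(amp[bins + 1, , drop = FALSE])

  out <- array(0, d[1:3])
  out[sm$idx] <- vals
  alff_map(out, band = c(f_lo, f_hi), mask = brain_mask,
           normalized = FALSE, voxel_size = series$voxel_size)
}

#' Normalize an ALFF map by its whole-brain mean
#'
#' Divides the map by its in-mask mean so the in-mask mean of the result
#' is 1. Removes global amplitude scale, so the normalized map is
#' invariant to any global rescaling of the raw series.
#'
#' @param map An [alff_map()].
#' @param brain_mask Mask to average over (defaults to the map's own mask).
#' @return The normalized [alff_map()].
#' @export
normalize_alff <- function(map, brain_mask = map$mask) {
  brain_mask <- check_mask(brain_mask, dim(map$data), "brain_mask")
  m <- mean(map$data[brain_mask])
  if (!is.finite(m) || m <= 0)
    stop("in-mask mean ALFF must be > 0 (all-zero map?)", call. = FALSE)
  map$data <- map$data / m
  map$data[!brain_mask] <- 0
  map$mask <- brain_mask
  map$normalized <- TRUE
  map
}
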