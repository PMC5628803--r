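# Shared fixture builders (all data generated in code at test time).

# Clean spectral phantom: noiseless, driftless, bin-aligned single
# oscillator with no between-subject jitter - the configuration under
# which amplitude recovery is exact.
clean_spec <- function(...) {
  phantom_spec(noise_sd = 0, drift_slope = 0, ar_coefficient = 0,
               n_oscillators = 1, amp_subject_sd = 0, bin_aligned = TRUE, ...)
}

# Small default cohort effects (all-null unless multipliers given).
null_effects <- function(n = 4) list(
  group_effect_spec("CTL", n),
  group_effect_spec("ACTL", n),
  group_effect_spec("SCD", n))

# Wrap a bare 3D array as a normalized-style alff_map for group-stats
# unit tests that construct maps directly.
as_map <- function(arr, mask = array(TRUE, dim(arr)), voxel_size = c(3, 3, 3)) {
  alff_map(arr, band = c(0.008, 0.09), mask = mask, normalized = TRUE,
           voxel_size = voxel_size)
}

# A list of n maps on a small grid with iid N(mu, sd) in-mask values.
random_maps <- function(n, dims = c(5, 5, 3), mu = 1, sd = 0.1,
                        mask = array(TRUE, dims), seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    arr <- array(0, dims)
    arr[mask] <- rnorm(sum(mask), mu, sd)
    as_map(arr, mask)
  }))
}

# Tiny single-voxel bold series from an explicit time series.
one_voxel_series <- function(y, tr = 2) {
  bold_series(array(y, c(1, 1, 1, length(y))), tr = tr, voxel_size = c(3, 3, 3))
}
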