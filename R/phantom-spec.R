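#' Phantom acquisition specification
#'
#' Describes a synthetic resting-state acquisition: grid geometry, timing,
#' the low-frequency band the planted oscillators live in, and the noise
#' model. Defaults emulate a short resting-state scan on a coarse common
#' grid: TR 2 s, 238 retained volumes, oscillators confined to
#' 0.008-0.09 Hz.
#'
#' Every gray-matter voxel receives `n_oscillators` sinusoids whose
#' frequencies are drawn uniformly in `osc_band` (or snapped to exact
#' Fourier bins when `bin_aligned = TRUE`, the debug mode used by spectral
#' oracles). Noise-compartment voxels (white matter, CSF, out-of-brain)
#' carry a shared per-subject confound waveform instead, scaled by
#' `confound_amplitude`, which CompCor is expected to recover;
#' `gray_confound_weight` optionally mixes that confound into gray matter
#' to exercise end-to-end confound removal.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of volumes to synthesize.
#' @param regions List of effect regions (see [default_regions()]); `NULL`
#'   resolves to the default two-region layout at simulation time.
#' @param baseline Mean signal level, arbitrary units.
#' @param osc_band Length-2 Hz, frequency range of planted oscillators.
#' @param n_oscillators Sinusoids per gray-matter voxel; each has the
#'   voxel's amplitude, so the planted in-band amplitude content is
#'   `n_oscillators * amplitude`.
#' @param background_amplitude Oscillator amplitude of gray voxels outside
#'   any effect region (signal units).
#' @param noise_sd Innovation standard deviation of the AR(1) voxel noise.
#' @param drift_slope Linear drift, signal units per volume.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param confound_amplitude Scale of the shared noise-compartment waveform.
#' @param gray_confound_weight Fraction of the confound mixed into gray
#'   voxels (0 = none).
#' @param amp_subject_sd Log-normal between-subject amplitude jitter (sd on
#'   the log scale), drawn independently for every oscillating voxel so
#'   that group maps carry no built-in spatial covariance; a subject's
#'   recorded regional truth is the realized mean amplitude over the
#'   region's voxels.
#' @param motion_walk_sd Per-step sd of the simulated motion random walk
#'   (mm for translations, degrees for rotations).
#' @param bin_aligned If `TRUE`, oscillator frequencies are drawn from exact
#'   Fourier bins of the acquisition.
#' @param seed Default master seed used when a caller does not provide one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12),
                         voxel_size = c(3, 3, 3),
                         tr = 2,
                         n_volumes = 238,
                         regions = NULL,
                         baseline = 100,
                         osc_band = c(0.008, 0.09),
                         n_oscillators = 3,
                         background_amplitude = 1,
                         noise_sd = 1,
                         drift_slope = 0.01,
                         ar_coefficient = 0.3,
                         confound_amplitude = 1,
                         gray_confound_weight = 0,
                         amp_subject_sd = 0.1,
                         motion_walk_sd = 0.02,
                         bin_aligned = FALSE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive", call. = FALSE)
  if (tr <= 0 || n_volumes < 3) stop("need tr > 0 and n_volumes >= 3", call. = FALSE)
  nyquist <- 1 / (2 * tr)
  if (!(osc_band[1] > 0 && osc_band[1] < osc_band[2] && osc_band[2] < nyquist))
    stop(sprintf("osc_band must satisfy 0 < f_lo < f_hi < Nyquist = %g Hz",
                 nyquist), call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must be in [0, 1)", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 tr = tr, n_volumes = as.integer(n_volumes), regions = regions,
                 baseline = baseline, osc_band = as.numeric(osc_band),
                 n_oscillators = as.integer(n_oscillators),
                 background_amplitude = background_amplitude,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 ar_coefficient = ar_coefficient,
                 confound_amplitude = confound_amplitude,
                 gray_confound_weight = gray_confound_weight,
                 amp_subject_sd = amp_subject_sd,
                 motion_walk_sd = motion_walk_sd,
                 bin_aligned = isTRUE(bin_aligned), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Group effect specification
#'
#' Encodes one cohort group's planted truth: how many subjects, which
#' effect regions have their oscillation amplitude multiplied (1 = no
#' effect), the age range, the score-generating model, and the rate of
#' pathological white-matter lesion load.
#'
#' @param group Group label, one of `"CTL"`, `"ACTL"`, `"SCD"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param amplitude_multiplier Named numeric, region id -> multiplicative
#'   amplitude factor; regions not named get 1.
#' @param age_range Length-2 numeric, years; ages are drawn uniformly.
#' @param score_model Named list; each element is a list with `mean`, `sd`
#'   and optionally `coupling` plus `region` (score units per signal unit
#'   of the region's true amplitude, centered at its expected value).
#' @param wmh_rate Probability that a subject carries a pathological lesion
#'   load (more than one lesion per decade of age).
#' @return An object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(group = c("CTL", "ACTL", "SCD"),
                              n_subjects = 8,
                              amplitude_multiplier = numeric(),
                              age_range = c(20, 45),
                              score_model = list(),
                              wmh_rate = 0.1) {
  group <- match.arg(group)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (length(amplitude_multiplier) && any(amplitude_multiplier <= 0))
    stop("amplitude_multiplier entries must be > 0", call. = FALSE)
  if (wmh_rate < 0 || wmh_rate > 1) stop("wmh_rate must be in [0, 1]", call. = FALSE)
  if (diff(age_range) < 0) stop("age_range must be increasing", call. = FALSE)
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 amplitude_multiplier = amplitude_multiplier,
                 age_range = as.numeric(age_range),
                 score_model = score_model, wmh_rate = wmh_rate),
            class = "group_effect_spec")
}

#' Default effect-region layout for a phantom
#'
#' Places compact effect regions inside the gray-matter shell: one anterior
#' ("frontal") and one posterior ("posterior") blob of `n_voxels` gray
#' voxels nearest to the corresponding pole of the gray shell. These are
#' the regions whose amplitudes group effects multiply.
#'
#' @param spec A [phantom_spec()].
#' @param masks Masks from [make_phantom_masks()]; computed if missing.
#' @param n_voxels Region size in voxels.
#' @param base_amplitude Oscillator amplitude of the region under a
#'   multiplier of 1 (signal units).
#' @return List of regions, each `list(id, voxels, base_amplitude)` with
#'   `voxels` as column-major linear indices into the grid.
#' @export
default_regions <- function(spec, masks = NULL, n_voxels = 30,
                            base_amplitude = spec$background_amplitude) {
  if (is.null(masks)) masks <- make_phantom_masks(spec)
  dims <- spec$grid_shape
  gray_idx <- which(masks$gray)
  if (length(gray_idx) < 2 * n_voxels)
    stop("gray mask too small for the default regions", call. = FALSE)
  ijk <- vox_ijk(gray_idx, dims)
  ctr <- (dims + 1) / 2
  nearest <- function(target) {
    d2 <- (ijk[, 1] - target[1])^2 + (ijk[, 2] - target[2])^2 +
      (ijk[, 3] - target[3])^2
    gray_idx[order(d2)][seq_len(n_voxels)]
  }
  front <- nearest(c(ctr[1], dims[2] - 1, ctr[3]))
  post <- nearest(c(ctr[1], 2, ctr[3]))
  list(list(id = "frontal", voxels = front, base_amplitude = base_amplitude),
       list(id = "posterior", voxels = post, base_amplitude = base_amplitude))
}

# Resolve regions lazily and check their invariants.
#' @noRd
resolve_regions <- function(spec, masks) {
  regions <- spec$regions %||% default_regions(spec, masks)
  seen <- integer(0)
  for (r in regions) {
    if (any(r$voxels %in% seen))
      stop("effect regions must be pairwise disjoint", call. = FALSE)
    if (!all(masks$brain[r$voxels]))
      stop(sprintf("region '%s' extends outside the brain mask", r$id),
           call. = FALSE)
    seen <- c(seen, r$voxels)
  }
  regions
}
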