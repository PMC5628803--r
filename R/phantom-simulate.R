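#' Build the phantom compartment masks
#'
#' Lays out a brain ellipsoid on the phantom grid with concentric tissue
#' compartments: a central white-matter core, a CSF shell around it, a
#' gray-matter outer shell, and a rectangular out-of-brain block in one
#' corner. White matter, CSF and the out-of-brain block are the three
#' noise regions-of-non-interest that CompCor pools; group inference runs
#' within the gray-matter mask.
#'
#' @param spec A [phantom_spec()].
#' @param min_compartment Minimum voxels each compartment must contain.
#' @return A list with logical arrays `brain`, `gray` and a list `noise`
#'   of three masks (`wm`, `csf`, `air`).
#' @export
make_phantom_masks <- function(spec, min_compartment = 8) {
  dims <- spec$grid_shape
  ctr <- (dims + 1) / 2
  semi <- c(0.40 * dims[1], 0.40 * dims[2], 0.38 * dims[3])
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  r <- sqrt(((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
              ((g$k - ctr[3]) / semi[3])^2)
  shape <- function(v) array(v, dim = dims)
  brain <- shape(r <= 1)
  wm <- shape(r <= 0.35)
  csf <- shape(r > 0.35 & r <= 0.45)
  gray <- shape(r > 0.55 & r <= 1)

  box <- c(max(2L, dims[1] %/% 5L), max(2L, dims[2] %/% 5L),
           max(2L, dims[3] %/% 3L))
  air <- shape(g$i <= box[1] & g$j <= box[2] & g$k <= box[3]) & !brain

  sizes <- c(brain = sum(brain), gray = sum(gray), wm = sum(wm),
             csf = sum(csf), air = sum(air))
  if (any(sizes < min_compartment))
    stop(sprintf(
      "configuration error: grid %s too small to allocate compartments of >= %d voxels (got %s)",
      paste(dims, collapse = "x"), min_compartment,
      paste(names(sizes), sizes, sep = "=", collapse = ", ")), call. = FALSE)
  list(brain = brain, gray = gray, noise = list(wm = wm, csf = csf, air = air))
}

#' Simulate a rigid-body head motion trace
#'
#' A clamped Gaussian random walk over 6 rigid-body parameters, starting at
#' zero: per-step standard deviation `walk_sd` (mm for translations,
#' degrees for rotations), with excursions clipped at `clamp_trans` mm and
#' `clamp_rot_deg` degrees. Also returns the per-volume 4x4 rigid affine
#' (rotation about the volume center, the phantom coordinate origin).
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param walk_sd Per-step sd, mm and degrees. `0` yields a motionless trace.
#' @param seed Integer seed; the trace is deterministic given it.
#' @param clamp_trans,clamp_rot_deg Walk bounds in mm / degrees.
#' @return A [motion_trace()].
#' @export
simulate_motion_trace <- function(n_volumes, walk_sd = 0.02, seed = 1L,
                                  clamp_trans = 1.0, clamp_rot_deg = 1.0) {
  if (n_volumes < 2) stop("n_volumes must be >= 2", call. = FALSE)
  if (walk_sd < 0) stop("walk_sd must be >= 0", call. = FALSE)
  params <- withr::with_seed(seed, {
    steps <- matrix(rnorm(n_volumes * 6, sd = walk_sd), n_volumes, 6)
    steps[1, ] <- 0
    p <- apply(steps, 2, cumsum)
    p[, 4:6] <- p[, 4:6] * pi / 180  # degrees -> radians
    p[, 1:3] <- pmin(pmax(p[, 1:3], -clamp_trans), clamp_trans)
    clamp_rot <- clamp_rot_deg * pi / 180
    p[, 4:6] <- pmin(pmax(p[, 4:6], -clamp_rot), clamp_rot)
    p
  })
  affines <- array(0, c(4, 4, n_volumes))
  for (v in seq_len(n_volumes)) affines[, , v] <- rigid_affine(params[v, ])
  motion_trace(params, affines)
}

# Draw a subject's simulation truth: age, per-voxel oscillator amplitudes
# (between-subject jitter is independent across voxels, so group maps have
# no built-in spatial covariance), lesion count and scores coupled to the
# subject's realized regional mean amplitude. Must run inside the
# subject's seeded RNG context.
#' @noRd
draw_subject_truth <- function(spec, effect, masks, regions, subject_id) {
  age <- runif(1, effect$age_range[1], effect$age_range[2])

  osc <- masks$brain & !masks$noise$wm & !masks$noise$csf
  osc_idx <- which(osc)
  amps_osc <- spec$background_amplitude *
    exp(rnorm(length(osc_idx), 0, spec$amp_subject_sd))
  region_names <- vapply(regions, `[[`, character(1), "id")
  realized <- numeric(length(regions))
  for (r in seq_along(regions)) {
    mult <- effect$amplitude_multiplier[region_names[r]]
    if (is.na(mult) || is.null(mult)) mult <- 1
    at <- match(regions[[r]]$voxels, osc_idx)
    amps_osc[at] <- regions[[r]]$base_amplitude * mult *
      exp(rnorm(length(at), 0, spec$amp_subject_sd))
    realized[r] <- mean(amps_osc[at])
  }
  names(realized) <- region_names

  decade <- floor(age / 10)
  pathological <- runif(1) < effect$wmh_rate
  wmh_count <- if (pathological) decade + 1 + rpois(1, 1) else
    rbinom(1, max(decade, 0), 0.3)

  scores <- lapply(names(effect$score_model), function(nm) {
    sm <- effect$score_model[[nm]]
    val <- sm$mean
    if (!is.null(sm$coupling) && !is.null(sm$region) &&
        sm$region %in% region_names) {
      mult <- effect$amplitude_multiplier[sm$region]
      if (is.na(mult) || is.null(mult)) mult <- 1
      expected <- regions[[match(sm$region, region_names)]]$base_amplitude * mult
      val <- val + sm$coupling * (realized[[sm$region]] - expected)
    }
    val + rnorm(1, 0, sm$sd)
  })
  names(scores) <- names(effect$score_model)

  record <- list(subject_id = subject_id, group = effect$group, age = age,
                 wmh_count = as.integer(wmh_count), scores = scores,
                 true_amplitudes = realized)
  list(record = record, osc_idx = osc_idx, amps_osc = amps_osc)
}

#' Simulate one subject's 4D BOLD phantom
#'
#' Synthesizes a full 4D series on the phantom grid. Gray-matter voxels
#' receive band-limited sinusoids whose amplitude is the region base
#' amplitude times the group multiplier (with per-subject log-normal
#' jitter); noise-compartment voxels carry a shared low-frequency plus
#' respiratory-like confound waveform; all brain voxels get baseline,
#' linear drift and AR(1) noise. The returned record stores the subject's
#' true per-region amplitudes - simulation truth that the analysis
#' pipeline never sees.
#'
#' @param spec A [phantom_spec()].
#' @param effect A [group_effect_spec()].
#' @param subject_seed Integer seed; output is deterministic given it.
#' @param subject_id Subject identifier (defaults to group + seed).
#' @param layout Optional precomputed `list(masks, regions)` to avoid
#'   recomputing geometry across subjects.
#' @return `list(bold, record)`: a [bold_series()] and the subject record.
#' @export
simulate_bold_subject <- function(spec, effect, subject_seed,
                                  subject_id = NULL, layout = NULL) {
  if (is.null(layout)) {
    masks <- make_phantom_masks(spec)
    layout <- list(masks = masks, regions = resolve_regions(spec, masks))
  }
  masks <- layout$masks
  regions <- layout$regions
  if (is.null(subject_id))
    subject_id <- sprintf("%s-%d", effect$group, subject_seed)

  dims <- spec$grid_shape
  nt <- spec$n_volumes
  nyquist <- 1 / (2 * spec$tr)
  if (spec$osc_band[2] >= nyquist)
    stop(sprintf("configuration error: osc_band upper edge %g Hz >= Nyquist %g Hz",
                 spec$osc_band[2], nyquist), call. = FALSE)

  osc <- masks$brain & !masks$noise$wm & !masks$noise$csf
  active_idx <- which(masks$brain | masks$noise$air)
  na <- length(active_idx)
  is_osc <- osc[active_idx]
  is_air <- masks$noise$air[active_idx]
  n_osc_vox <- sum(is_osc)
  J <- spec$n_oscillators

  sim <- withr::with_seed(subject_seed, {
    truth <- draw_subject_truth(spec, effect, masks, regions, subject_id)
    record <- truth$record

    amps <- numeric(na)
    amps[match(truth$osc_idx, active_idx)] <- truth$amps_osc

    freqs <- matrix(0, na, J)
    if (spec$bin_aligned) {
      fk <- seq_len(floor(nt / 2)) / (nt * spec$tr)
      bins <- which(fk >= spec$osc_band[1] & fk <= spec$osc_band[2])
      if (!length(bins))
        stop("configuration error: no Fourier bin inside osc_band", call. = FALSE)
      freqs[is_osc, ] <- fk[sample(bins, n_osc_vox * J, replace = TRUE)]
    } else {
      freqs[is_osc, ] <- runif(n_osc_vox * J, spec$osc_band[1], spec$osc_band[2])
    }
    phases <- matrix(runif(na * J, 0, 2 * pi), na, J)

    tsec <- (seq_len(nt) - 1) * spec$tr
    ph <- runif(2, 0, 2 * pi)
    confound <- spec$confound_amplitude *
      (sin(2 * pi * 0.032 * tsec + ph[1]) + 0.7 * sin(2 * pi * 0.12 * tsec + ph[2]))
    confound_w <- numeric(na)
    confound_w[!is_osc] <- 1
    confound_w[is_osc] <- spec$gray_confound_weight

    baseline <- ifelse(is_air, 0.05 * spec$baseline, spec$baseline)
    drift <- ifelse(is_air, 0, spec$drift_slope)
    noise_seed <- derive_seed()

    s <- synth_signals_cpp(nt, spec$tr, freqs, phases, amps, baseline, drift,
                           spec$noise_sd, spec$ar_coefficient, confound,
                           confound_w, noise_seed)
    list(record = record, s = s)
  })

  full <- matrix(0, prod(dims), nt)
  full[active_idx, ] <- t(sim$s)
  bold <- bold_series(array(full, c(dims, nt)), tr = spec$tr,
                      voxel_size = spec$voxel_size, validate = FALSE)
  list(bold = bold, record = sim$record)
}

#' Simulate a multi-group phantom cohort
#'
#' Derives one reproducible seed per subject from `master_seed`, simulates
#' each subject's BOLD series and motion trace, and assembles the cohort
#' table (subject id, group, age, lesion count, scores). With `map_fn`
#' given, each subject's series is replaced by `map_fn(bold, record)`
#' immediately after simulation, so long cohort runs never hold more than
#' one 4D series in memory.
#'
#' @param spec A [phantom_spec()].
#' @param effects List of [group_effect_spec()], one per group (>= 2
#'   groups, each with >= 2 subjects).
#' @param master_seed Integer master seed.
#' @param map_fn Optional `function(bold, record)` applied per subject.
#' @return List with `bold` (list of series or `map_fn` results), `motion`
#'   (list of [motion_trace()]), `cohort` (data frame), `records`, and the
#'   shared `layout` (masks + regions).
#' @export
simulate_cohort <- function(spec, effects, master_seed = spec$seed,
                            map_fn = NULL) {
  if (length(effects) < 2) stop("need at least 2 groups", call. = FALSE)
  masks <- make_phantom_masks(spec)
  layout <- list(masks = masks, regions = resolve_regions(spec, masks))

  ids <- unlist(lapply(effects, function(e)
    sprintf("%s%02d", e$group, seq_len(e$n_subjects))))
  if (anyDuplicated(ids))
    stop("generation error: duplicate subject ids (duplicate group labels?)",
         call. = FALSE)
  n_total <- length(ids)

  seeds <- withr::with_seed(master_seed, {
    list(subject = derive_seed(n_total), motion = derive_seed(n_total))
  })

  bold <- vector("list", n_total)
  motion <- vector("list", n_total)
  records <- vector("list", n_total)
  s <- 0L
  for (e in effects) {
    for (i in seq_len(e$n_subjects)) {
      s <- s + 1L
      motion[[s]] <- simulate_motion_trace(spec$n_volumes, spec$motion_walk_sd,
                                           seed = seeds$motion[s])
      sub <- simulate_bold_subject(spec, e, seeds$subject[s],
                                   subject_id = ids[s], layout = layout)
      records[[s]] <- sub$record
      bold[[s]] <- if (is.null(map_fn)) sub$bold else
        map_fn(sub$bold, sub$record)
    }
  }
  names(bold) <- names(motion) <- names(records) <- ids

  score_names <- unique(unlist(lapply(records, function(r) names(r$scores))))
  cohort <- data.frame(
    subject_id = ids,
    group = vapply(records, `[[`, character(1), "group"),
    age = vapply(records, `[[`, numeric(1), "age"),
    wmh_count = vapply(records, `[[`, integer(1), "wmh_count"),
    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in score_names)
    cohort[[nm]] <- vapply(records, function(r)
      if (!is.null(r$scores[[nm]])) r$scores[[nm]] else NA_real_, numeric(1))

  list(bold = bold, motion = motion, cohort = cohort, records = records,
       layout = layout)
}
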