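#' Default pipeline configuration
#'
#' A nested list collecting every stage parameter: discard count,
#' slice-timing toggle, motion threshold (mm), grand-mean target,
#' smoothing FWHM (mm), CompCor component count, analysis band (Hz),
#' Monte-Carlo correction settings and test levels, plus the simulation
#' block describing the synthetic cohort. Every stochastic stage has an
#' explicit seed derived from the top-level `seed`.
#'
#' @param seed Master seed for the run.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      grid_shape = c(24, 24, 12), voxel_size = c(3, 3, 3), tr = 2,
      n_volumes = 240, noise_sd = 1, drift_slope = 0.01,
      ar_coefficient = 0.3, gray_confound_weight = 0,
      groups = list(
        list(group = "CTL", n_subjects = 4),
        list(group = "ACTL", n_subjects = 4),
        list(group = "SCD", n_subjects = 4,
             amplitude_multiplier = c(frontal = 1.5), wmh_rate = 0.5))),
    preprocess = list(n_discard = 2, slice_timing = TRUE, ref_fraction = 0.5,
                      rms_threshold = 1.5, rms_radius = 80,
                      normalize_target = 10000, fwhm = 8, n_compcor = 5),
    alff = list(band = c(0.008, 0.09)),
    groupstats = list(null_value = 1, voxel_p = 0.05, alpha = 0.05,
                      mc_fwhm = 4, mc_iter = 2000,
                      posthoc = list(c("SCD", "CTL"), c("SCD", "ACTL"))),
    brainbehavior = list(deficit_groups = c("SCD", "CTL"), score_alpha = 0.05,
                         fdr_q = 0.05)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  config <- default_pipeline_config(seed = raw$seed %||% 1L)
  for (sec in intersect(names(raw), names(config))) {
    if (is.list(config[[sec]]) && is.list(raw[[sec]]))
      config[[sec]] <- modifyList(config[[sec]], raw[[sec]])
    else config[[sec]] <- raw[[sec]]
  }
  validate_pipeline_config(config)
}

#' Validate a pipeline configuration (fail-fast)
#'
#' Checks every parameter against its stage's preconditions before any
#' computation: the analysis band must sit below the Nyquist frequency,
#' thresholds and levels must be in range, and each stochastic stage must
#' have a seed.
#'
#' @param config A `pipeline_config` list.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_pipeline_config <- function(config) {
  tr <- config$simulate$tr
  nyq <- 1 / (2 * tr)
  band <- as.numeric(config$alff$band)
  if (length(band) != 2 || band[1] < 0 || band[1] >= band[2] || band[2] > nyq)
    stop(sprintf("alff$band [%s] invalid for Nyquist %g Hz",
                 paste(band, collapse = ", "), nyq), call. = FALSE)
  if (config$preprocess$rms_threshold <= 0)
    stop("preprocess$rms_threshold must be > 0", call. = FALSE)
  if (config$preprocess$n_discard < 0)
    stop("preprocess$n_discard must be >= 0", call. = FALSE)
  gs <- config$groupstats
  if (gs$voxel_p <= 0 || gs$voxel_p >= 1 || gs$alpha <= 0 || gs$alpha >= 1)
    stop("groupstats voxel_p/alpha must be in (0, 1)", call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  invisible(config)
}

#' Write a simulated cohort to disk
#'
#' Writes every subject's 4D series (NIfTI-1, optional), motion TSVs, the
#' compartment masks and the cohort table into `out_dir`, in the layout
#' the downstream stages read.
#'
#' @param sim Result of [simulate_cohort()].
#' @param spec The [phantom_spec()] the cohort was simulated from.
#' @param out_dir Output directory.
#' @param write_bold Write the 4D series files (default TRUE).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_outputs <- function(sim, spec, out_dir, write_bold = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  masks <- sim$layout$masks
  write_map_nifti(masks$brain, file.path(out_dir, "brain_mask.nii.gz"),
                  spec$voxel_size)
  write_map_nifti(masks$gray, file.path(out_dir, "gray_mask.nii.gz"),
                  spec$voxel_size)
  for (nm in names(masks$noise))
    write_map_nifti(masks$noise[[nm]],
                    file.path(out_dir, sprintf("noise_%s_mask.nii.gz", nm)),
                    spec$voxel_size)
  write_cohort_tsv(sim$cohort, file.path(out_dir, "cohort.tsv"))
  for (id in sim$cohort$subject_id) {
    write_motion_tsv(sim$motion[[id]],
                     file.path(out_dir, sprintf("%s_motion.tsv", id)))
    if (write_bold && inherits(sim$bold[[id]], "bold_series"))
      write_bold_nifti(sim$bold[[id]],
                       file.path(out_dir, sprintf("%s_bold.nii.gz", id)))
  }
  invisible(out_dir)
}

# Drop the leading rows of a motion trace to match discarded volumes.
#' @noRd
trim_motion <- function(trace, n_discard) {
  if (n_discard == 0) return(trace)
  motion_trace(trace$params[-seq_len(n_discard), , drop = FALSE],
               trace$affines[, , -seq_len(n_discard), drop = FALSE])
}

#' Preprocess one subject's series
#'
#' Applies the functional preprocessing chain in order: discard initial
#' volumes, slice-timing correction, grand-mean intensity normalization,
#' Gaussian smoothing, CompCor component extraction (from the unsmoothed,
#' normalized series, so smoothing cannot leak gray-matter signal into the
#' noise compartments), and the 17-regressor nuisance GLM.
#'
#' @param bold A [bold_series()].
#' @param trace The subject's [motion_trace()] (full acquisition length).
#' @param masks Mask list as returned by [make_phantom_masks()].
#' @param prep The `preprocess` section of a pipeline config.
#' @return List with the residual `series`, the `design`, and `components`.
#' @export
preprocess_subject <- function(bold, trace, masks,
                               prep = default_pipeline_config()$preprocess) {
  s <- discard_initial_volumes(bold, prep$n_discard)
  if (isTRUE(prep$slice_timing))
    s <- slice_timing_correct(s, ref_fraction = prep$ref_fraction %||% 0.5)
  s <- normalize_intensity(s, masks$brain, target = prep$normalize_target)
  comps <- compcor_components(s, masks$noise, n_components = prep$n_compcor)
  if (prep$fwhm > 0) s <- smooth_gaussian(s, fwhm = prep$fwhm)
  tr_trim <- trim_motion(trace, prep$n_discard)
  design <- build_nuisance_design(tr_trim, comps)
  s <- suppressWarnings(regress_nuisance(s, design, masks$brain))
  list(series = s, design = design, components = comps)
}

#' Run the full analysis pipeline
#'
#' Simulates a phantom cohort, preprocesses every subject, computes
#' normalized ALFF maps, runs the group statistics (within-group
#' one-sample t, age-adjusted ANCOVA with Monte-Carlo cluster-extent
#' correction, post-hoc contrasts, lesion subgroup test) and the
#' brain-behavior correlation stage, writing every intermediate artifact
#' and a JSON run manifest under `out_dir`. Re-running with the same
#' config reproduces the outputs bit-identically.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_bold Write per-subject 4D NIfTI files (default TRUE;
#'   disable to save space in large simulated runs).
#' @return Invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         write_bold = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  # --- simulate -------------------------------------------------------
  sim_cfg <- config$simulate
  spec_args <- sim_cfg[setdiff(names(sim_cfg), "groups")]
  spec <- do.call(phantom_spec, spec_args)
  effects <- lapply(sim_cfg$groups, function(g) do.call(group_effect_spec, g))
  sim <- simulate_cohort(spec, effects, master_seed = config$seed)
  masks <- sim$layout$masks
  ids <- sim$cohort$subject_id
  log_line("simulate: %d subjects on a %s grid, %d volumes",
           length(ids), paste(spec$grid_shape, collapse = "x"), spec$n_volumes)

  sim_dir <- file.path(out_dir, "sim")
  write_cohort_outputs(sim, spec, sim_dir, write_bold = write_bold)

  # --- motion QC ------------------------------------------------------
  prep <- config$preprocess
  qc <- qc_filter(sim$motion, threshold = prep$rms_threshold,
                  radius = prep$rms_radius)
  qc_tab <- data.frame(subject_id = names(qc$max_rms),
                       max_rms_mm = as.numeric(qc$max_rms),
                       kept = names(qc$max_rms) %in% qc$kept)
  write.table(qc_tab, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_line("qc: %d kept, %d excluded at %.2g mm", length(qc$kept),
           length(qc$excluded), prep$rms_threshold)
  kept <- qc$kept
  if (length(kept) < 6) stop("too few subjects survive motion QC", call. = FALSE)

  # --- preprocess + ALFF ---------------------------------------------
  band <- as.numeric(config$alff$band)
  alff_dir <- file.path(out_dir, "alff")
  dir.create(alff_dir, showWarnings = FALSE)
  alff_maps <- list()
  for (id in kept) {
    pp <- preprocess_subject(sim$bold[[id]], sim$motion[[id]], masks, prep)
    amap <- normalize_alff(compute_alff(pp$series, band[1], band[2],
                                        masks$brain))
    write_map_nifti(amap$data,
                    file.path(alff_dir, sprintf("%s_alff_norm.nii.gz", id)),
                    spec$voxel_size)
    alff_maps[[id]] <- amap
  }
  log_line("alff: %d normalized maps, band %.3f-%.3f Hz", length(alff_maps),
           band[1], band[2])

  cohort <- sim$cohort[match(kept, sim$cohort$subject_id), , drop = FALSE]
  groups <- cohort$group

  # --- group statistics ----------------------------------------------
  gs <- config$groupstats
  gray <- masks$gray
  # separate extent thresholds: one-sided null for the ANCOVA F map,
  # sign-separated two-sided null for the t maps
  kmin_f <- mc_cluster_threshold(gray,
    mc_threshold_spec(voxel_p = gs$voxel_p, fwhm = gs$mc_fwhm,
                      alpha = gs$alpha, n_iter = gs$mc_iter,
                      seed = config$seed + 1L, sided = "one"),
    spec$voxel_size)
  kmin_t <- mc_cluster_threshold(gray,
    mc_threshold_spec(voxel_p = gs$voxel_p, fwhm = gs$mc_fwhm,
                      alpha = gs$alpha, n_iter = gs$mc_iter,
                      seed = config$seed + 2L, sided = "two"),
    spec$voxel_size)
  kmin <- kmin_f
  log_line("mc threshold: F clusters >= %d, t clusters >= %d voxels (voxel p %.3g, fwhm %g mm, alpha %.3g)",
           as.integer(kmin_f), as.integer(kmin_t), gs$voxel_p, gs$mc_fwhm,
           gs$alpha)

  stats_dir <- file.path(out_dir, "groupstats")
  dir.create(stats_dir, showWarnings = FALSE)
  onesample <- list()
  for (gp in unique(groups)) {
    gmaps <- alff_maps[groups == gp]
    if (length(gmaps) < 3) next
    tm <- suppressWarnings(one_sample_tmap(gmaps, null_value = gs$null_value,
                                           mask = gray))
    write_map_nifti(tm$data,
                    file.path(stats_dir, sprintf("onesample_%s_t.nii.gz", gp)),
                    spec$voxel_size)
    ct <- extract_clusters(tm, gs$voxel_p, kmin_t)
    write_cluster_tsv(ct, file.path(stats_dir,
                                    sprintf("onesample_%s_clusters.tsv", gp)))
    onesample[[gp]] <- list(tmap = tm, clusters = ct)
  }

  fmap <- ancova_fmap(alff_maps, groups, cohort$age, gray)
  write_map_nifti(fmap$data, file.path(stats_dir, "ancova_F.nii.gz"),
                  spec$voxel_size)
  anc_clusters <- extract_clusters(fmap, gs$voxel_p, kmin_f)
  write_cluster_tsv(anc_clusters, file.path(stats_dir, "ancova_clusters.tsv"))
  log_line("ancova: %d cluster(s) at corrected alpha %.3g", nrow(anc_clusters),
           gs$alpha)

  sig_mask <- array(FALSE, spec$grid_shape)
  for (vox in attr(anc_clusters, "voxels")) sig_mask[vox] <- TRUE
  posthoc <- list()
  for (pair in gs$posthoc) {
    if (!all(pair %in% groups)) next
    key <- paste(pair, collapse = "_vs_")
    tm <- suppressWarnings(posthoc_tmap(alff_maps, groups, pair[1], pair[2],
                                        sig_mask))
    ct <- extract_clusters(tm, gs$voxel_p, kmin_t)
    write_map_nifti(tm$data,
                    file.path(stats_dir, sprintf("posthoc_%s_t.nii.gz", key)),
                    spec$voxel_size)
    write_cluster_tsv(ct, file.path(stats_dir,
                                    sprintf("posthoc_%s_clusters.tsv", key)))
    posthoc[[key]] <- list(tmap = tm, clusters = ct)
  }

  wmh <- NULL
  scd <- cohort$subject_id[cohort$group == "SCD"]
  if (length(scd) >= 4 && nrow(anc_clusters) > 0) {
    flags <- classify_wmh_pathological(
      cohort$wmh_count[match(scd, cohort$subject_id)],
      cohort$age[match(scd, cohort$subject_id)])
    if (sum(flags) >= 2 && sum(!flags) >= 2) {
      wmh <- wmh_subgroup_test(alff_maps[scd], flags, anc_clusters,
                               voxel_p = gs$voxel_p,
                               min_cluster_voxels = kmin_t)
      write.table(wmh$summary, file.path(stats_dir, "wmh_subgroup.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else log_line("wmh: subgroup too small (%d flagged); test skipped",
                    sum(flags))
  }

  # --- brain-behavior -------------------------------------------------
  bb <- config$brainbehavior
  correlations <- NULL
  if (nrow(anc_clusters) > 0) {
    dg <- bb$deficit_groups
    sel <- suppressWarnings(select_deficit_scores(cohort, dg[1], dg[2],
                                                  alpha = bb$score_alpha))
    regional <- regional_alff_matrix(alff_maps, anc_clusters)
    if (length(sel)) {
      correlations <- correlate_clusters_scores(cohort, regional, sel,
                                                q = bb$fdr_q)
      write.table(correlations, file.path(out_dir, "correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else log_line("brainbehavior: no deficit scores selected")
  }

  # --- manifest -------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "alffpipe",
    version = as.character(utils::packageVersion("alffpipe")),
    seed = config$seed,
    config = unclass(config),
    n_subjects = length(ids), n_kept = length(kept),
    excluded = qc$excluded,
    mc_min_cluster_voxels = list(F = as.integer(kmin_f),
                                 t = as.integer(kmin_t)),
    n_ancova_clusters = nrow(anc_clusters),
    outputs = as.list(stats::setNames(as.character(tools::md5sum(outputs)),
                                      sub(paste0(out_dir, "/"), "", outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("pipeline complete: %d output files under %s", length(outputs),
           out_dir)
  invisible(list(manifest = manifest, qc = qc, alff = alff_maps,
                 onesample = onesample, ancova = fmap,
                 ancova_clusters = anc_clusters, posthoc = posthoc,
                 wmh = wmh, correlations = correlations, cohort = cohort,
                 min_cluster_voxels = c(F = as.integer(kmin_f),
                                        t = as.integer(kmin_t))))
}
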