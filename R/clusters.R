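#' Label connected components of a 3D mask
#'
#' Connected-component labeling under face (6), edge (18) or corner (26)
#' adjacency. Face adjacency is the default throughout the package, the
#' classic nearest-neighbor clustering rule for statistical maps.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array of labels, 0 outside components.
#' @export
label_components <- function(mask, connectivity = 6) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array", call. = FALSE)
  lab <- label_components_cpp(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  array(lab, d)
}

#' Monte-Carlo cluster-threshold settings
#'
#' Parameters of the AlphaSim-style correction: the per-voxel threshold,
#' the assumed smoothness of the null field, the corrected familywise
#' alpha, and the number of null simulations.
#'
#' @param voxel_p Two-sided per-voxel p threshold (default 0.05).
#' @param fwhm Smoothness of the simulated null field in mm (default 4).
#' @param alpha Corrected familywise error level (default 0.05).
#' @param n_iter Number of Monte-Carlo iterations (>= 1000; default 10000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param connectivity Cluster adjacency (6, 18 or 26).
#' @param sided `"two"` (t maps: positive and negative excursions at
#'   `voxel_p / 2` each, clustered separately - matching how
#'   [extract_clusters()] treats t maps) or `"one"` (F maps: a single
#'   suprathreshold class at rate `voxel_p`). The null cluster sizes are
#'   systematically larger one-sided, so the setting must match the map
#'   being corrected.
#' @return An object of class `mc_threshold_spec`.
#' @export
mc_threshold_spec <- function(voxel_p = 0.05, fwhm = 4, alpha = 0.05,
                              n_iter = 10000, seed = 1L, connectivity = 6,
                              sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (voxel_p <= 0 || voxel_p >= 1 || alpha <= 0 || alpha >= 1)
    stop("voxel_p and alpha must be in (0, 1)", call. = FALSE)
  if (n_iter < 1000) stop("n_iter must be >= 1000", call. = FALSE)
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  structure(list(voxel_p = voxel_p, fwhm = fwhm, alpha = alpha,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 connectivity = connectivity, sided = sided),
            class = "mc_threshold_spec")
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the null distribution of the largest suprathreshold cluster:
#' each iteration fills the mask's bounding grid with unit Gaussian noise,
#' smooths it to the assumed FWHM, re-standardizes within the mask,
#' thresholds at the `voxel_p` quantile (two-sided with sign-separated
#' clustering for t maps, one-sided for F maps - set `sided` in the
#' [mc_threshold_spec()] to match [extract_clusters()]'s treatment of the
#' map), and records the largest in-mask cluster. The returned extent is
#' the smallest integer `k` such that the empirical probability of a
#' maximum cluster of `k` or more voxels is at most `alpha`.
#'
#' @param mask Logical 3D analysis mask.
#' @param mc An [mc_threshold_spec()].
#' @param voxel_size Voxel size in mm (converts `fwhm` to voxels).
#' @return Integer minimum cluster extent in voxels, with attributes
#'   `tail_prob` (the attained familywise rate) and `max_sizes` (the
#'   simulated null maxima).
#' @export
mc_cluster_threshold <- function(mask, mc, voxel_size = c(1, 1, 1)) {
  d <- dim(mask)
  if (length(d) != 3L || !any(mask)) stop("mask must be a non-empty 3D array",
                                          call. = FALSE)
  if (mc$n_iter * mc$alpha < 5)
    stop("n_iter too small for the requested alpha (need n_iter * alpha >= 5)",
         call. = FALSE)
  sigma <- fwhm_to_sigma(mc$fwhm) / voxel_size
  Ks <- lapply(1:3, function(a) if (sigma[a] > 1e-8)
    gauss_conv_matrix(d[a], sigma[a]) else NULL)
  sided <- mc$sided %||% "two"
  zq <- if (sided == "two") qnorm(1 - mc$voxel_p / 2) else
    qnorm(1 - mc$voxel_p)
  signs <- if (sided == "two") c(1, -1) else 1
  idx <- which(mask)

  max_sizes <- withr::with_seed(mc$seed, {
    vapply(seq_len(mc$n_iter), function(it) {
      z <- array(rnorm(prod(d)), d)
      for (a in 1:3) if (!is.null(Ks[[a]])) z <- apply_axis(z, Ks[[a]], a)
      zi <- z[idx]
      zi <- (zi - mean(zi)) / sd(zi)
      biggest <- 0L
      for (sgn in signs) {
        supra <- array(FALSE, d)
        supra[idx] <- sgn * zi > zq
        if (any(supra)) {
          lab <- label_components_cpp(supra, as.integer(d),
                                      as.integer(mc$connectivity))
          biggest <- max(biggest, max(tabulate(lab)))
        }
      }
      biggest
    }, integer(1))
  })

  k <- 1L
  while (mean(max_sizes >= k) > mc$alpha) k <- k + 1L
  structure(k, tail_prob = mean(max_sizes >= k), max_sizes = max_sizes)
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds a statistic map at the per-voxel `voxel_p` level (two-sided
#' for t maps, with positive and negative clusters labeled separately;
#' one-sided for F maps), labels connected components, drops clusters
#' smaller than `min_cluster_voxels`, and reports per-cluster size, peak
#' location and mean statistic. Non-finite statistics (degenerate-variance
#' voxels) are excluded from clustering with a message.
#'
#' mm coordinates are `(index - 1) * voxel_size` on the common grid.
#'
#' @param stat A [stat_map()].
#' @param voxel_p Per-voxel p threshold.
#' @param min_cluster_voxels Minimum cluster extent in voxels.
#' @param connectivity Cluster adjacency (default 6, face adjacency).
#' @return A `cluster_table` data frame with columns `cluster_id`, `sign`,
#'   `size_voxels`, `size_mm3`, `peak_i/j/k`, `peak_x/y/z_mm`, `peak_stat`,
#'   `mean_stat`; cluster voxel indices are kept in `attr(, "voxels")`.
#' @export
extract_clusters <- function(stat, voxel_p = 0.05, min_cluster_voxels = 1,
                             connectivity = 6) {
  d <- dim(stat$data)
  thr <- stat_threshold(stat, voxel_p)
  vals <- stat$data
  ok <- stat$mask & is.finite(vals)
  n_bad <- sum(stat$mask) - sum(ok)
  if (n_bad > 0)
    message(sprintf("excluding %d non-finite statistic voxel(s) from clustering",
                    n_bad))

  rows <- list()
  voxlist <- list()
  signs <- if (stat$stat_kind == "t") c(1, -1) else 1
  vol <- prod(stat$voxel_size)
  for (sgn in signs) {
    supra <- ok & (sgn * vals > thr)
    if (!any(supra)) next
    lab <- label_components(supra, connectivity)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      if (length(vox) < min_cluster_voxels) next
      st <- vals[vox]
      pk <- vox[which.max(abs(st))]
      ijk <- vox_ijk(pk, d)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        size_voxels = length(vox), size_mm3 = length(vox) * vol,
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
        peak_x_mm = (ijk[1] - 1) * stat$voxel_size[1],
        peak_y_mm = (ijk[2] - 1) * stat$voxel_size[2],
        peak_z_mm = (ijk[3] - 1) * stat$voxel_size[3],
        peak_stat = st[which.max(abs(st))], mean_stat = mean(st),
        stringsAsFactors = FALSE)
      voxlist[[length(voxlist) + 1L]] <- vox
    }
  }
  if (!length(rows)) {
    tab <- data.frame(cluster_id = integer(0), sign = character(0),
                      size_voxels = integer(0), size_mm3 = numeric(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_stat = numeric(0), mean_stat = numeric(0))
  } else {
    tab <- do.call(rbind, rows)
    o <- order(-tab$size_voxels)
    tab <- tab[o, , drop = FALSE]
    voxlist <- voxlist[o]
    tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  }
  structure(tab, voxels = voxlist, voxel_size = stat$voxel_size,
            class = c("cluster_table", "data.frame"))
}

# Statistic threshold corresponding to a per-voxel p.
#' @noRd
stat_threshold <- function(stat, voxel_p) {
  if (stat$stat_kind == "t") qt(1 - voxel_p / 2, stat$df) else
    qf(1 - voxel_p, stat$df[1], stat$df[2])
}

#' Mean ALFF over a cluster
#'
#' @param map An [alff_map()].
#' @param cluster Integer vector of column-major voxel indices (as stored
#'   in a `cluster_table`'s `voxels` attribute) or a logical 3D mask.
#' @return Arithmetic mean of the map over the cluster voxels.
#' @export
cluster_mean_alff <- function(map, cluster) {
  if (is.logical(cluster) || is.array(cluster)) cluster <- which(cluster != 0)
  cluster <- as.integer(cluster)
  if (!length(cluster)) stop("cluster is empty", call. = FALSE)
  if (any(cluster < 1 | cluster > length(map$data)))
    stop("cluster indices outside the grid", call. = FALSE)
  mean(map$data[cluster])
}

#' Per-subject regional mean ALFF matrix
#'
#' @param maps List of [alff_map()] on a common grid.
#' @param clusters A `cluster_table` from [extract_clusters()].
#' @return Numeric matrix, subjects x clusters (columns named by
#'   `cluster_id`).
#' @export
regional_alff_matrix <- function(maps, clusters) {
  voxlist <- attr(clusters, "voxels")
  out <- vapply(voxlist, function(vox)
    vapply(maps, cluster_mean_alff, numeric(1), cluster = vox),
    numeric(length(maps)))
  out <- matrix(out, nrow = length(maps))
  colnames(out) <- paste0("cluster", clusters$cluster_id)
  rownames(out) <- names(maps)
  out
}
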