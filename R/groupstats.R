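# Stack a list of alff_map into a voxel x subject matrix over a mask.
#' @noRd
maps_matrix <- function(maps, mask) {
  d <- dim(maps[[1]]$data)
  for (m in maps) if (!identical(dim(m$data), d))
    stop("maps must share one grid", call. = FALSE)
  idx <- which(mask)
  y <- vapply(maps, function(m) m$data[idx], numeric(length(idx)))
  list(y = matrix(y, nrow = length(idx)), idx = idx, dims = d)
}

#' Voxelwise one-sample t map
#'
#' Tests, at every in-mask voxel, whether the mean map value differs from
#' `null_value`. For normalized ALFF maps the natural null is 1, the
#' within-mask global mean: positive t marks voxels whose amplitude sits
#' above the subject's global mean. Zero-variance voxels get a statistic
#' of +/-Inf (0 if the mean equals the null) with a warning.
#'
#' @param maps List of [alff_map()] (>= 3).
#' @param null_value Null mean (default 1).
#' @param mask Logical analysis mask.
#' @return A [stat_map()] of t statistics with `df = n - 1`.
#' @export
one_sample_tmap <- function(maps, null_value = 1, mask) {
  n <- length(maps)
  if (n < 3) stop("need at least 3 maps", call. = FALSE)
  mm <- maps_matrix(maps, mask)
  mu <- rowMeans(mm$y)
  ss <- (rowSums(mm$y^2) - n * mu^2) / (n - 1)
  ss[ss < 0] <- 0
  se <- sqrt(ss / n)
  tvals <- (mu - null_value) / se
  degen <- se == 0
  if (any(degen)) {
    warning(sprintf("%d voxel(s) with zero variance; statistic set to 0 or +/-Inf",
                    sum(degen)))
    tvals[degen] <- sign(mu[degen] - null_value) * Inf
    tvals[degen & mu == null_value] <- 0
  }
  out <- array(0, mm$dims)
  out[mm$idx] <- tvals
  stat_map(out, df = n - 1, stat_kind = "t", mask = mask,
           voxel_size = maps[[1]]$voxel_size)
}

#' Voxelwise ANCOVA F map (group effect, age-adjusted)
#'
#' Per voxel, fits the linear model `value ~ group + age` by ordinary
#' least squares and tests the group factor by the extra sum of squares
#' against the age-only model: `F` with `df = (g - 1, n - g - 1)`.
#' Voxels where both models fit perfectly (identical maps) get F = 0 with
#' a warning.
#'
#' @param maps List of [alff_map()], one per subject.
#' @param groups Factor or character vector of group labels.
#' @param age Numeric vector of ages (the covariate).
#' @param mask Logical analysis mask.
#' @return A [stat_map()] of F statistics.
#' @export
ancova_fmap <- function(maps, groups, age, mask) {
  n <- length(maps)
  groups <- factor(groups)
  g <- nlevels(groups)
  if (length(groups) != n || length(age) != n)
    stop("groups and age must match the number of maps", call. = FALSE)
  if (g < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  if (n <= g + 1) stop("need n > number of groups + 1", call. = FALSE)

  X1 <- model.matrix(~ groups + age)
  if (qr(X1)$rank < ncol(X1))
    stop("age is collinear with the group indicators in the voxelwise design",
         call. = FALSE)
  X0 <- model.matrix(~ age)
  mm <- maps_matrix(maps, mask)
  Y <- t(mm$y)  # subjects x voxels
  rss1 <- colSums(qr.resid(qr(X1), Y)^2)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  df1 <- g - 1
  df2 <- n - g - 1
  fvals <- ((rss0 - rss1) / df1) / (rss1 / df2)

  tot <- colSums(scale(Y, scale = FALSE)^2)
  degen <- tot <= 1e-16 * pmax(colSums(Y^2), 1e-300)
  if (any(degen)) {
    warning(sprintf("%d degenerate voxel(s) (no variance); F set to 0",
                    sum(degen)))
    fvals[degen] <- 0
  }
  fvals[!degen & !is.finite(fvals) & rss1 <= 1e-16 * tot] <- Inf
  out <- array(0, mm$dims)
  out[mm$idx] <- fvals
  stat_map(out, df = c(df1, df2), stat_kind = "F", mask = mask,
           voxel_size = maps[[1]]$voxel_size)
}

#' Post-hoc two-sample t map
#'
#' Voxelwise two-sample t between two groups, restricted to a mask of
#' voxels already declared significant (typically the union of ANCOVA
#' clusters). Pooled-variance t by default; positive values mean
#' `group_a > group_b`.
#'
#' @param maps List of [alff_map()], one per subject.
#' @param groups Group labels aligned with `maps`.
#' @param group_a,group_b The two groups to contrast.
#' @param significant_mask Logical mask of voxels to test.
#' @param var_equal Pooled (`TRUE`, default) or Welch t.
#' @return A [stat_map()] of t statistics (empty mask gives an empty map
#'   with a warning).
#' @export
posthoc_tmap <- function(maps, groups, group_a, group_b, significant_mask,
                         var_equal = TRUE) {
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 subjects", call. = FALSE)
  if (!any(significant_mask)) {
    warning("significant_mask is empty; returning an empty statistic map")
    return(stat_map(array(0, dim(maps[[1]]$data)),
                    df = length(ia) + length(ib) - 2, stat_kind = "t",
                    mask = significant_mask,
                    voxel_size = maps[[1]]$voxel_size))
  }
  mm <- maps_matrix(maps, significant_mask)
  ya <- mm$y[, ia, drop = FALSE]
  yb <- mm$y[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- (rowSums(ya^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(yb^2) - nb * mb^2) / (nb - 1)
  va[va < 0] <- 0; vb[vb < 0] <- 0
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df <- mean(df[is.finite(df)])  # map-level Welch df summary
  }
  tvals <- (ma - mb) / se
  degen <- se == 0
  if (any(degen)) {
    tvals[degen] <- sign(ma[degen] - mb[degen]) * Inf
    tvals[degen & ma == mb] <- 0
  }
  out <- array(0, mm$dims)
  out[mm$idx] <- tvals
  stat_map(out, df = df, stat_kind = "t", mask = significant_mask,
           voxel_size = maps[[1]]$voxel_size)
}

#' Lesion-load subgroup test within clusters
#'
#' Second-level analysis: within each input cluster, a voxelwise
#' two-sample t between subjects with and without a pathological
#' white-matter lesion load, followed by sub-cluster extraction at the
#' stated voxel p and extent rule. Positive t means the flagged subgroup
#' is higher.
#'
#' @param maps List of [alff_map()] for the subgroup's subjects.
#' @param wmh_flags Logical vector aligned with `maps` (pathological or not).
#' @param clusters A `cluster_table` of first-level clusters.
#' @param voxel_p Per-voxel p for sub-cluster extraction.
#' @param min_cluster_voxels Extent rule for sub-clusters.
#' @param var_equal Pooled (default) or Welch t.
#' @return List with `summary` (per input cluster: subgroup sizes and mean
#'   t over the cluster) and `subclusters` (a `cluster_table`-style data
#'   frame with a `parent_cluster` column).
#' @export
wmh_subgroup_test <- function(maps, wmh_flags, clusters, voxel_p = 0.05,
                              min_cluster_voxels = 1, var_equal = TRUE) {
  wmh_flags <- as.logical(wmh_flags)
  if (length(wmh_flags) != length(maps))
    stop("wmh_flags must align with maps", call. = FALSE)
  if (sum(wmh_flags) < 2 || sum(!wmh_flags) < 2)
    stop("both lesion subgroups need >= 2 subjects", call. = FALSE)
  voxlist <- attr(clusters, "voxels")
  d <- dim(maps[[1]]$data)
  groups <- ifelse(wmh_flags, "with", "without")

  summaries <- list()
  subrows <- list()
  for (ci in seq_len(nrow(clusters))) {
    cmask <- array(FALSE, d)
    cmask[voxlist[[ci]]] <- TRUE
    tmap <- posthoc_tmap(maps, groups, "with", "without", cmask,
                         var_equal = var_equal)
    tv <- tmap$data[cmask]
    summaries[[ci]] <- data.frame(
      parent_cluster = clusters$cluster_id[ci],
      n_with = sum(wmh_flags), n_without = sum(!wmh_flags),
      mean_t = mean(tv[is.finite(tv)]), stringsAsFactors = FALSE)
    sub <- extract_clusters(tmap, voxel_p = voxel_p,
                            min_cluster_voxels = min_cluster_voxels)
    if (nrow(sub)) {
      sub <- cbind(parent_cluster = clusters$cluster_id[ci],
                   as.data.frame(sub))
      subrows[[length(subrows) + 1L]] <- sub
    }
  }
  list(summary = do.call(rbind, summaries),
       subclusters = if (length(subrows)) do.call(rbind, subrows) else
         data.frame())
}
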