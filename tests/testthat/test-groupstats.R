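test_that("one-sample t map reproduces the hand-computed statistic", {
  dims <- c(3, 3, 2)
  mask <- array(TRUE, dims)
  maps <- lapply(c(1.1, 1.2, 1.3, 1.4, 1.5), function(v)
    as_map(array(v, dims), mask))
  tm <- one_sample_tmap(maps, null_value = 1, mask = mask)
  # mean 1.3, sd 0.15811, t = 0.3 / (sd/sqrt(5)) = 4.2426
  expect_equal(tm$data[1, 1, 1], 4.242640687, tolerance = 1e-8)
  expect_equal(tm$df, 4)

  # subject order is irrelevant
  tm2 <- one_sample_tmap(maps[c(3, 1, 5, 2, 4)], null_value = 1, mask = mask)
  expect_equal(tm2$data, tm$data)

  expect_error(one_sample_tmap(maps[1:2], mask = mask), "at least 3")
})

test_that("one-sample t map handles zero-variance voxels per policy", {
  dims <- c(2, 2, 1)
  mask <- array(TRUE, dims)
  maps <- lapply(1:4, function(i) {
    arr <- array(1, dims)       # exactly the null everywhere
    arr[2, 2, 1] <- 1.5         # above-null, still zero variance
    as_map(arr, mask)
  })
  expect_warning(tm <- one_sample_tmap(maps, null_value = 1, mask = mask),
                 "zero variance")
  expect_equal(tm$data[1, 1, 1], 0)
  expect_equal(tm$data[2, 2, 1], Inf)
})

test_that("ANCOVA F agrees with lm()/anova() and the F = t^2 identity", {
  dims <- c(3, 3, 1)
  mask <- array(TRUE, dims)
  n <- 14
  groups <- rep(c("CTL", "SCD"), each = 7)
  withr::with_seed(77, {
    age <- runif(n, 20, 50)
    maps <- lapply(seq_len(n), function(i)
      as_map(array(rnorm(prod(dims), 1, 0.1), dims), mask))
  })
  fm <- ancova_fmap(maps, groups, age, mask)
  expect_equal(fm$df, c(1, 11))
  g <- factor(groups)
  for (i in seq_len(prod(dims))) {
    y <- vapply(maps, function(m) m$data[i], numeric(1))
    fit <- lm(y ~ g + age)
    f_lm <- anova(lm(y ~ age), fit)$F[2]
    expect_equal(fm$data[i], f_lm, tolerance = 1e-8)
    t_lm <- summary(fit)$coefficients["gSCD", "t value"]
    expect_equal(fm$data[i], t_lm^2, tolerance = 1e-8)
  }
})

test_that("ANCOVA attains its nominal voxelwise level under the null", {
  dims <- c(10, 10, 20)  # 2000 independent voxels
  mask <- array(TRUE, dims)
  n <- 18
  groups <- rep(c("CTL", "ACTL", "SCD"), each = 6)
  withr::with_seed(42, {
    age <- runif(n, 20, 50)
    maps <- lapply(seq_len(n), function(i)
      as_map(array(rnorm(prod(dims), 1, 0.1), dims), mask))
  })
  fm <- ancova_fmap(maps, groups, age, mask)
  rate <- mean(fm$data[mask] > qf(0.95, fm$df[1], fm$df[2]))
  expect_lt(abs(rate - 0.05), 0.02)  # 2000 voxels: se ~ 0.005
})

test_that("ANCOVA rejects collinear covariates and degenerate data", {
  dims <- c(2, 2, 1)
  mask <- array(TRUE, dims)
  maps <- lapply(1:8, function(i) as_map(array(1, dims), mask))
  groups <- rep(c("A", "B"), each = 4)
  age_collinear <- c(rep(30, 4), rep(40, 4))
  expect_error(ancova_fmap(maps, groups, age_collinear, mask), "collinear")

  age <- c(29, 31, 30, 32, 39, 41, 40, 42)
  expect_warning(fm <- ancova_fmap(maps, groups, age, mask), "degenerate")
  expect_equal(max(abs(fm$data)), 0)
})

test_that("post-hoc t reproduces the pooled hand computation and is antisymmetric", {
  dims <- c(2, 2, 1)
  mask <- array(TRUE, dims)
  vals <- list(2, 3, 4, 1, 2, 3)
  maps <- lapply(vals, function(v) as_map(array(v, dims), mask))
  groups <- rep(c("a", "b"), each = 3)
  tm <- posthoc_tmap(maps, groups, "a", "b", mask)
  expect_equal(tm$data[1, 1, 1], 1.224744871, tolerance = 1e-8)
  expect_equal(tm$df, 4)

  tm_rev <- posthoc_tmap(maps, groups, "b", "a", mask)
  expect_equal(tm_rev$data, -tm$data)

  # identical group data: t = 0 everywhere
  same <- posthoc_tmap(c(maps[1:3], maps[1:3]), groups, "a", "b", mask)
  expect_equal(max(abs(same$data)), 0)

  expect_warning(out <- posthoc_tmap(maps, groups, "a", "b",
                                     array(FALSE, dims)), "empty")
  expect_equal(sum(out$mask), 0)
})

test_that("cluster extraction obeys extent, adjacency and bookkeeping rules", {
  dims <- c(10, 10, 4)
  mask <- array(TRUE, dims)
  arr <- array(0, dims)
  arr[2:6, 2:3, 1] <- 5          # a 10-voxel blob (face-connected)
  stat <- stat_map(arr, df = 20, stat_kind = "t", mask = mask,
                   voxel_size = c(3, 3, 3))
  ct <- extract_clusters(stat, voxel_p = 0.05, min_cluster_voxels = 5)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$size_voxels, 10)
  expect_equal(ct$size_mm3, 10 * 27)
  expect_equal(ct$sign, "positive")

  expect_equal(nrow(extract_clusters(stat, 0.05, min_cluster_voxels = 11)), 0)

  # two blobs touching only at a corner are distinct under face adjacency
  arr2 <- array(0, dims)
  arr2[2:3, 2:3, 2] <- 5
  arr2[4:5, 4:5, 3] <- 5   # corner/edge contact across axes only
  stat2 <- stat_map(arr2, df = 20, stat_kind = "t", mask = mask,
                    voxel_size = c(3, 3, 3))
  ct2 <- extract_clusters(stat2, 0.05, 1)
  expect_equal(nrow(ct2), 2)
  expect_equal(sort(ct2$size_voxels), c(4, 4))

  # negative clusters labeled separately, sign recorded
  arr3 <- arr2
  arr3[8:9, 8:9, 1] <- -6
  stat3 <- stat_map(arr3, df = 20, stat_kind = "t", mask = mask,
                    voxel_size = c(3, 3, 3))
  ct3 <- extract_clusters(stat3, 0.05, 1)
  expect_equal(sum(ct3$sign == "negative"), 1)
  expect_equal(ct3$mean_stat[ct3$sign == "negative"], -6)
})

test_that("component labeling agrees with a pure-R flood-fill oracle", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      mask <- array(runif(8 * 7 * 6) < 0.3, c(8, 7, 6))
      mine <- label_components(mask)
      oracle <- flood_fill_labels(mask)
      # same partition: sizes match and labels are a bijection
      expect_equal(sort(tabulate(mine[mine > 0])),
                   sort(tabulate(oracle[oracle > 0])))
      expect_equal(max(mine), max(oracle))
      key <- paste(mine[mask], oracle[mask])
      expect_equal(length(unique(key)), max(mine))
    }
  })
})

test_that("Monte-Carlo threshold matches an independent oracle at zero smoothness", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8))
  gray <- make_phantom_masks(spec)$gray
  mc <- mc_threshold_spec(voxel_p = 0.05, fwhm = 0, alpha = 0.05,
                          n_iter = 1000, seed = 404)
  mine <- mc_cluster_threshold(gray, mc, c(3, 3, 3))
  oracle <- mc_threshold_oracle(gray, 0.05, 0.05, 1000, seed = 404)
  expect_lte(abs(as.integer(mine) - oracle), 1)

  mc1 <- mc_threshold_spec(voxel_p = 0.05, fwhm = 0, alpha = 0.05,
                           n_iter = 1000, seed = 404, sided = "one")
  mine1 <- mc_cluster_threshold(gray, mc1, c(3, 3, 3))
  oracle1 <- mc_threshold_oracle(gray, 0.05, 0.05, 1000, seed = 404,
                                 sided = "one")
  expect_lte(abs(as.integer(mine1) - oracle1), 1)
  # one-sided null clusters are systematically at least as large
  expect_gte(as.integer(mine1), as.integer(mine))
})

test_that("Monte-Carlo threshold is monotone in alpha and smoothness", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8))
  gray <- make_phantom_masks(spec)$gray
  k05 <- mc_cluster_threshold(gray,
    mc_threshold_spec(alpha = 0.05, fwhm = 0, n_iter = 1000, seed = 7),
    c(3, 3, 3))
  k01 <- mc_cluster_threshold(gray,
    mc_threshold_spec(alpha = 0.01, fwhm = 0, n_iter = 1000, seed = 7),
    c(3, 3, 3))
  expect_lte(as.integer(k05), as.integer(k01))

  k_smooth <- mc_cluster_threshold(gray,
    mc_threshold_spec(alpha = 0.05, fwhm = 6, n_iter = 1000, seed = 7),
    c(3, 3, 3))
  expect_gte(as.integer(k_smooth), as.integer(k05))

  expect_error(mc_cluster_threshold(gray,
    mc_threshold_spec(alpha = 0.001, n_iter = 1000, seed = 1), c(3, 3, 3)),
    "n_iter")
})

test_that("cluster means obey the size-weighted union identity", {
  dims <- c(5, 5, 2)
  arr <- array(seq_len(prod(dims)), dims)
  map <- as_map(arr)
  expect_equal(cluster_mean_alff(map, c(1, 2, 3)), 2)
  c1 <- 1:4
  c2 <- 10:15
  pooled <- cluster_mean_alff(map, c(c1, c2))
  weighted <- (4 * cluster_mean_alff(map, c1) + 6 * cluster_mean_alff(map, c2)) / 10
  expect_equal(pooled, weighted)
  expect_error(cluster_mean_alff(map, integer(0)), "empty")
  expect_error(cluster_mean_alff(map, prod(dims) + 1), "grid")
})

test_that("the lesion subgroup test recovers a planted decrement", {
  dims <- c(10, 10, 4)
  mask <- array(TRUE, dims)
  blob <- array(0, dims)
  blob[3:6, 3:6, 2] <- 8
  stat <- stat_map(blob, df = 20, stat_kind = "t", mask = mask,
                   voxel_size = c(3, 3, 3))
  clusters <- extract_clusters(stat, 0.05, 5)
  cvox <- attr(clusters, "voxels")[[1]]

  withr::with_seed(55, {
    maps <- lapply(1:12, function(i) {
      arr <- array(rnorm(prod(dims), 1, 0.05), dims)
      if (i <= 6) arr[cvox] <- arr[cvox] - 0.5   # flagged subjects lower
      as_map(arr, mask)
    })
  })
  flags <- rep(c(TRUE, FALSE), each = 6)
  res <- wmh_subgroup_test(maps, flags, clusters, voxel_p = 0.05,
                           min_cluster_voxels = 2)
  expect_equal(res$summary$parent_cluster, clusters$cluster_id[1])
  expect_lt(res$summary$mean_t, -3)
  expect_gt(nrow(res$subclusters), 0)
  expect_true(all(res$subclusters$sign == "negative"))

  expect_error(wmh_subgroup_test(maps, rep(TRUE, 12), clusters), ">= 2")
})

test_that("the lesion subgroup test stays quiet under the null", {
  dims <- c(10, 10, 4)
  mask <- array(TRUE, dims)
  blob <- array(0, dims)
  blob[3:6, 3:6, 2] <- 8
  stat <- stat_map(blob, df = 20, stat_kind = "t", mask = mask,
                   voxel_size = c(3, 3, 3))
  clusters <- extract_clusters(stat, 0.05, 5)
  cmask <- array(FALSE, dims)
  cmask[attr(clusters, "voxels")[[1]]] <- TRUE
  kmin <- mc_cluster_threshold(cmask,
    mc_threshold_spec(fwhm = 0, n_iter = 1000, seed = 9), c(3, 3, 3))

  flags <- rep(c(TRUE, FALSE), each = 6)
  empties <- withr::with_seed(31, vapply(1:60, function(rep) {
    maps <- lapply(1:12, function(i)
      as_map(array(rnorm(prod(dims), 1, 0.05), dims), mask))
    res <- wmh_subgroup_test(maps, flags, clusters, voxel_p = 0.05,
                             min_cluster_voxels = as.integer(kmin))
    nrow(res$subclusters) == 0
  }, logical(1)))
  expect_gte(mean(empties), 0.9)  # corrected FWER 5% nominal
})
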