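test_that("initial-volume discard drops exactly the leading volumes", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_volumes = 240,
                       noise_sd = 0.5)
  sub <- simulate_bold_subject(spec, group_effect_spec("CTL", 4), 1)
  out <- discard_initial_volumes(sub$bold, 2)
  expect_equal(n_volumes(out), 238)
  expect_equal(out$data[, , , 1], sub$bold$data[, , , 3])
  expect_equal(out$tr, sub$bold$tr)
  expect_identical(discard_initial_volumes(sub$bold, 0), sub$bold)

  small <- bold_series(array(1, c(2, 2, 2, 5)), tr = 2, voxel_size = c(3, 3, 3))
  expect_error(discard_initial_volumes(small, 5), "n_discard")
})

test_that("slice-timing correction is exact for trivial cases", {
  arr <- array(rnorm(4 * 4 * 3 * 20), c(4, 4, 3, 20))
  s <- bold_series(arr, tr = 2, voxel_size = c(3, 3, 3))
  # reference at the first slice's acquisition time, one-slice axis:
  # all slices share one acquisition time -> identity
  one_slice <- bold_series(array(arr[, , 1, , drop = FALSE], c(4, 4, 1, 20)),
                           tr = 2, voxel_size = c(3, 3, 3))
  out <- slice_timing_correct(one_slice, ref_fraction = 0)
  expect_equal(out$data, one_slice$data, tolerance = 1e-12)

  # constant-in-time voxels are unchanged under any shift
  const <- bold_series(array(rep(rnorm(4 * 4 * 3), 20), c(4, 4, 3, 20)),
                       tr = 2, voxel_size = c(3, 3, 3))
  out <- slice_timing_correct(const)
  expect_equal(out$data, const$data, tolerance = 1e-12)

  expect_error(slice_timing_correct(s, slice_order = c(1, 1, 3)),
               "permutation")
})

test_that("slice-timing correction matches the phase-shifted sinusoid", {
  tr <- 2
  nt <- 60
  f <- 0.05
  nsl <- 4
  tt <- (seq_len(nt) - 1) * tr
  arr <- array(0, c(1, 1, nsl, nt))
  for (s in seq_len(nsl)) {
    t_acq <- tt + (s - 1) / nsl * tr
    arr[1, 1, s, ] <- sin(2 * pi * f * t_acq)
  }
  series <- bold_series(arr, tr = tr, voxel_size = c(3, 3, 3))
  out <- slice_timing_correct(series, ref_fraction = 0.5)
  expected <- sin(2 * pi * f * (tt + 0.5 * tr))
  tol <- (2 * pi * f * tr)^2 / 8 * 1.1  # linear-interpolation error bound
  for (s in seq_len(nsl)) {
    err <- max(abs(out$data[1, 1, s, 3:(nt - 2)] - expected[3:(nt - 2)]))
    expect_lt(err, tol)
  }
})

test_that("motion RMS has the closed-form properties", {
  expect_equal(motion_rms(diag(4), diag(4)), 0)
  tr_aff <- diag(4)
  tr_aff[1:3, 4] <- c(1, 2, 2)
  expect_equal(motion_rms(tr_aff, diag(4), radius = 80), 3.0)
  expect_equal(motion_rms(tr_aff, diag(4), radius = 10), 3.0)  # radius-free
  # symmetry
  rot <- alffpipe:::rigid_affine(c(0.3, -0.2, 0.1, 0.004, -0.003, 0.002))
  expect_equal(motion_rms(rot, diag(4)), motion_rms(diag(4), rot),
               tolerance = 1e-12)
  expect_error(motion_rms(matrix(0, 4, 4), diag(4)), "invertible")
})

test_that("motion RMS matches a Monte-Carlo ball-sampling oracle", {
  withr::with_seed(99, {
    for (i in 1:8) {
      p <- c(runif(3, -0.3, 0.3), runif(3, -0.004, 0.004))
      a <- alffpipe:::rigid_affine(p)
      closed <- motion_rms(a, diag(4), radius = 80)
      mc <- rms_ball_oracle(a, diag(4), radius = 80, n = 1e5, seed = 100 + i)
      expect_lt(abs(closed - mc), 1e-3)
    }
  })
})

test_that("QC filter excludes by max RMS with a monotone threshold", {
  still <- simulate_motion_trace(20, walk_sd = 0, seed = 1)
  jump <- still
  jump$affines[1:3, 4, 10] <- c(2, 0, 0)
  jump$params[10, 1] <- 2
  traces <- list(calm = still, mover = jump)

  qc <- qc_filter(traces, threshold = 1.5)
  expect_equal(qc$kept, "calm")
  expect_equal(qc$excluded, "mover")
  expect_equal(unname(qc$max_rms["mover"]), 2.0)

  all_in <- qc_filter(traces, threshold = Inf)
  expect_equal(sort(all_in$kept), c("calm", "mover"))
  # raising the threshold never drops a previously kept subject
  for (thr in c(0.5, 1, 1.9, 2.5)) {
    lo <- qc_filter(traces, threshold = thr)$kept
    hi <- qc_filter(traces, threshold = thr + 0.5)$kept
    expect_true(all(lo %in% hi))
  }
})

test_that("Gaussian smoothing preserves constants, mass, and kernel width", {
  dims <- c(33, 33, 33)
  arr <- array(0, dims)
  expect_identical(smooth_gaussian(arr, fwhm = 0, voxel_size = c(1, 1, 1)), arr)

  const <- array(7, dims)
  out <- smooth_gaussian(const, fwhm = 6, voxel_size = c(1, 1, 1))
  expect_equal(out, const, tolerance = 1e-12)

  delta <- array(0, dims)
  delta[17, 17, 17] <- 1
  sm <- smooth_gaussian(delta, fwhm = 6, voxel_size = c(1, 1, 1))
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # interior impulse: mass kept
  profile <- sm[, 17, 17]
  half <- max(profile) / 2
  above <- which(profile >= half)
  # linear interpolation of the half-max crossings
  lo <- min(above); hi <- max(above)
  x_lo <- lo - 1 + (half - profile[lo - 1]) / (profile[lo] - profile[lo - 1])
  x_hi <- hi + (profile[hi] - half) / (profile[hi] - profile[hi + 1])
  expect_equal(x_hi - x_lo, 6, tolerance = 0.6)  # within 10% of nominal

  # anisotropic voxels: width in mm is isotropic
  sm2 <- smooth_gaussian(array(delta, dims), fwhm = 6, voxel_size = c(2, 1, 1))
  px <- sm2[, 17, 17]
  ax <- which(px >= max(px) / 2)
  expect_lt(length(ax), length(above))  # fewer 2 mm voxels span the same mm
})

test_that("grand-mean normalization is a single global rescale", {
  spec <- phantom_spec(grid_shape = c(12, 12, 8), n_volumes = 20)
  masks <- make_phantom_masks(spec)
  sub <- simulate_bold_subject(spec, group_effect_spec("CTL", 4), 2)
  out <- normalize_intensity(sub$bold, masks$brain, target = 10000)
  sm <- alffpipe:::series_matrix(out, masks$brain)
  expect_equal(mean(sm$y), 10000, tolerance = 1e-9)
  ratio <- out$data[masks$brain] / sub$bold$data[, , , 1][masks$brain]
  # idempotence
  out2 <- normalize_intensity(out, masks$brain, target = 10000)
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  zero <- bold_series(array(0, c(4, 4, 2, 5)), tr = 2, voxel_size = c(3, 3, 3))
  expect_error(normalize_intensity(zero, array(TRUE, c(4, 4, 2))), "grand mean")
})

test_that("CompCor recovers a planted shared confound", {
  spec <- phantom_spec(grid_shape = c(16, 16, 10), n_volumes = 100,
                       noise_sd = 0.2, confound_amplitude = 2)
  masks <- make_phantom_masks(spec)
  sub <- simulate_bold_subject(spec, group_effect_spec("CTL", 4), 31)
  comps <- compcor_components(sub$bold, masks$noise, n_components = 5)
  expect_equal(dim(comps), c(100, 5))
  expect_equal(unname(crossprod(comps)), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)

  # component 1 should track the planted shared waveform; the detrended
  # mean noise-ROI series is that waveform up to O(noise_sd/sqrt(V)) error
  pooled <- masks$noise$wm | masks$noise$csf | masks$noise$air
  sm <- alffpipe:::series_matrix(sub$bold, pooled)
  mean_series <- rowMeans(alffpipe:::detrend_linear(sm$y))
  expect_gt(abs(cor(comps[, 1], mean_series)), 0.99)

  expect_error(compcor_components(sub$bold,
                                  list(array(FALSE, spec$grid_shape)),
                                  n_components = 5), "noise voxels")
})

test_that("the nuisance design has 17 labeled columns with backward differences", {
  trace <- simulate_motion_trace(50, walk_sd = 0.05, seed = 4)
  comps <- matrix(rnorm(50 * 5), 50, 5,
                  dimnames = list(NULL, paste0("compcor", 1:5)))
  des <- build_nuisance_design(trace, comps)
  expect_equal(ncol(des$matrix), 17)
  expect_equal(des$labels[1:6], c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_equal(unname(des$matrix[1, 7:12]), rep(0, 6))
  expect_equal(des$matrix[2:50, "dtx"],
               trace$params[2:50, "tx"] - trace$params[1:49, "tx"],
               ignore_attr = TRUE)

  still <- simulate_motion_trace(50, walk_sd = 0, seed = 1)
  des0 <- build_nuisance_design(still, comps)
  expect_equal(max(abs(des0$matrix[, 7:12])), 0)

  expect_error(build_nuisance_design(trace, comps[1:40, ]), "match")
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  nt <- 60
  trace <- simulate_motion_trace(nt, walk_sd = 0.05, seed = 9)
  comps <- matrix(rnorm(nt * 5), nt, 5)
  des <- build_nuisance_design(trace, comps)
  dims <- c(4, 4, 2)
  mask <- array(TRUE, dims)
  arr <- array(rnorm(prod(dims) * nt, mean = 100), c(dims, nt))
  # one voxel exactly equal to a design column + constant
  arr[1, 1, 1, ] <- 50 + 3 * des$matrix[, "compcor1"]
  s <- bold_series(arr, tr = 2, voxel_size = c(3, 3, 3))
  out <- regress_nuisance(s, des, mask)

  resid1 <- out$data[1, 1, 1, ]
  expect_lt(sd(resid1), 1e-10)  # perfect fit: zero fluctuation
  expect_equal(mean(resid1), mean(arr[1, 1, 1, ]), tolerance = 1e-10)

  sm <- alffpipe:::series_matrix(out, mask)
  centered <- sweep(sm$y, 2, colMeans(sm$y), "-")
  dots <- abs(crossprod(des$matrix, centered))
  # relative to the design-column and data norms; the perfect-fit voxel has
  # an all-zero residual, so floor the residual norm at a fraction of the
  # data norm to keep the ratio meaningful
  ynorm <- sqrt(colSums(sweep(alffpipe:::series_matrix(s, mask)$y, 2,
                              colMeans(alffpipe:::series_matrix(s, mask)$y),
                              "-")^2))
  norms <- outer(sqrt(colSums(des$matrix^2)),
                 pmax(sqrt(colSums(centered^2)), 1e-6 * ynorm))
  expect_lt(max(dots / norms), 1e-8)
})

test_that("degenerate designs are pruned and an empty model demeans+remeans", {
  nt <- 40
  still <- simulate_motion_trace(nt, walk_sd = 0, seed = 1)
  comps <- matrix(0, nt, 5)
  des <- build_nuisance_design(still, comps)  # every column constant
  arr <- array(rnorm(2 * 2 * 2 * nt, 10), c(2, 2, 2, nt))
  s <- bold_series(arr, tr = 2, voxel_size = c(3, 3, 3))
  expect_warning(out <- regress_nuisance(s, des, array(TRUE, c(2, 2, 2))),
                 "pruned")
  expect_equal(out$data, s$data, tolerance = 1e-10)  # intercept-only model
})

test_that("a planted gray-matter confound is attenuated by the nuisance GLM", {
  spec <- phantom_spec(grid_shape = c(16, 16, 10), n_volumes = 120,
                       noise_sd = 0.5, confound_amplitude = 2,
                       gray_confound_weight = 0.8)
  masks <- make_phantom_masks(spec)
  sub <- simulate_bold_subject(spec, group_effect_spec("CTL", 4), 17)
  trace <- simulate_motion_trace(120, walk_sd = 0.02, seed = 17)
  comps <- compcor_components(sub$bold, masks$noise, 5)
  des <- build_nuisance_design(trace, comps)
  cleaned <- regress_nuisance(sub$bold, des, masks$brain)

  pooled <- masks$noise$wm | masks$noise$csf
  conf_proxy <- rowMeans(alffpipe:::detrend_linear(
    alffpipe:::series_matrix(sub$bold, pooled)$y))
  gray_idx <- which(masks$gray)[seq(1, sum(masks$gray), by = 37)]
  d <- dim(cleaned$data)
  before <- after <- numeric(length(gray_idx))
  raw <- matrix(sub$bold$data, prod(d[1:3]), d[4])
  cln <- matrix(cleaned$data, prod(d[1:3]), d[4])
  for (i in seq_along(gray_idx)) {
    before[i] <- abs(cor(raw[gray_idx[i], ], conf_proxy))
    after[i] <- abs(cor(cln[gray_idx[i], ], conf_proxy))
  }
  expect_gt(mean(before), 0.5)   # the confound really contaminates gray
  expect_lt(mean(after), 0.1)    # and regression removes it
})
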