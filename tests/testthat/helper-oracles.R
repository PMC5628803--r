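# Independent oracles used across tests. These deliberately re-derive
# results from definitions (explicit O(T^2) sums, lm(), flood fill,
# Monte-Carlo sampling) rather than calling the package's own code paths.

# Brute-force one-sided amplitude spectrum and band-averaged ALFF for a
# single series: lm()-based band-protected detrend, explicit DFT sums.
brute_alff <- function(y, tr, f_lo, f_hi) {
  nt <- length(y)
  k_all <- seq_len(floor(nt / 2))
  fk <- k_all / (nt * tr)
  bins <- k_all[fk >= f_lo & fk <= f_hi]
  tt <- 0:(nt - 1)
  tc <- seq_len(nt) - (nt + 1) / 2
  S <- do.call(cbind, lapply(bins, function(k)
    cbind(sin(2 * pi * k * tt / nt), cos(2 * pi * k * tt / nt))))
  ct <- stats::resid(stats::lm(tc ~ S))
  slope <- sum(ct * y) / sum(ct * tc)
  yd <- y - mean(y) - slope * tc
  amps <- vapply(bins, function(k) {
    re <- sum(yd * cos(2 * pi * k * tt / nt))
    im <- sum(yd * sin(2 * pi * k * tt / nt))
    fac <- if (nt %% 2 == 0 && k == nt / 2) 1 else 2
    fac * sqrt(re^2 + im^2) / nt
  }, numeric(1))
  list(alff = mean(amps), amps = amps, bins = bins, detrended = yd)
}

# One-sided amplitude at a single Fourier bin, no detrending at all.
brute_bin_amplitude <- function(y, k) {
  nt <- length(y)
  tt <- 0:(nt - 1)
  re <- sum(y * cos(2 * pi * k * tt / nt))
  im <- sum(y * sin(2 * pi * k * tt / nt))
  2 * sqrt(re^2 + im^2) / nt
}

# Exhaustive definition-based Benjamini-Hochberg: reject the largest set
# {p_(1)..p_(k)} with p_(k) <= k q / m; adjusted p by the step-up minimum.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_star <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_star <- k
  reject_sorted <- seq_len(m) <= k_star
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adjusted <- reject <- numeric(m)
  adjusted[o] <- adj_sorted
  reject[o] <- reject_sorted
  list(adjusted = adjusted, reject = as.logical(reject))
}

# Pure-R flood-fill connected components, face adjacency.
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cz <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      cy <- rem %/% d[1]
      cx <- rem %% d[1]
      for (n in seq_len(nrow(nbr))) {
        x <- cx + nbr[n, 1]; y <- cy + nbr[n, 2]; z <- cz + nbr[n, 3]
        if (x < 0 || x >= d[1] || y < 0 || y >= d[2] || z < 0 || z >= d[3]) next
        idx <- 1L + x + d[1] * (y + d[2] * z)
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- lab
          stack <- c(stack, idx)
        }
      }
    }
  }
  labels
}

# Monte-Carlo RMS displacement over a solid sphere: sample points
# uniformly in the ball (antithetic pairs +/-x for variance reduction),
# apply the relative transform, average the squared displacement.
rms_ball_oracle <- function(affine_a, affine_b, radius, center = c(0, 0, 0),
                            n = 1e5, seed = 1) {
  m <- solve(affine_b) %*% affine_a
  withr::with_seed(seed, {
    half <- ceiling(n / 2)
    u <- matrix(rnorm(3 * half), half, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * runif(half)^(1 / 3)
    pts <- rbind(u * r, -u * r)
    pts <- sweep(pts, 2, center, "+")
    moved <- pts %*% t(m[1:3, 1:3]) +
      matrix(m[1:3, 4], nrow(pts), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - pts)^2)))
  })
}

# Independent AlphaSim-style threshold for smoothness 0: identical noise
# stream (full-grid draws, standardized within mask) but R flood fill and
# explicit tail bookkeeping.
mc_threshold_oracle <- function(mask, voxel_p, alpha, n_iter, seed,
                                sided = "two") {
  d <- dim(mask)
  idx <- which(mask)
  zq <- if (sided == "two") qnorm(1 - voxel_p / 2) else qnorm(1 - voxel_p)
  sgns <- if (sided == "two") c(1, -1) else 1
  maxs <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      z <- array(rnorm(prod(d)), d)
      zi <- z[idx]
      zi <- (zi - mean(zi)) / sd(zi)
      big <- 0L
      for (sgn in sgns) {
        supra <- array(FALSE, d)
        supra[idx] <- sgn * zi > zq
        labs <- flood_fill_labels(supra)
        if (max(labs) > 0L) big <- max(big, max(tabulate(labs)))
      }
      big
    }, integer(1))
  })
  k <- 1L
  while (mean(maxs >= k) > alpha) k <- k + 1L
  k
}
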