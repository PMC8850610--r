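# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and the signal/matrix shortcuts they use): explicit loops,
# normal equations, direct-form IIR filtering.

# framewise displacement by an explicit per-frame loop
bf_fd <- function(motion, head_radius_mm = 50) {
  n <- nrow(motion)
  fd <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(motion[t, j] - motion[t - 1, j])
    for (j in 4:6) s <- s + head_radius_mm * abs(motion[t, j] - motion[t - 1, j])
    fd[t] <- s
  }
  fd
}

# Pearson correlation from explicit mean/covariance loops
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# OLS betas by normal equations, one voxel at a time
bf_glm_betas <- function(Y, X) {
  XtXi <- solve(t(X) %*% X)
  B <- matrix(0, ncol(Y), ncol(X))
  for (v in seq_len(ncol(Y))) B[v, ] <- XtXi %*% t(X) %*% Y[, v]
  B
}

# direct-form IIR filtering (transposed direct form II as a plain loop)
bf_iir <- function(b, a, x) {
  n <- length(x); y <- numeric(n)
  nb <- length(b); na <- length(a)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nb)) if (t - j + 1 >= 1) acc <- acc + b[j] * x[t - j + 1]
    for (j in 2:na) if (t - j + 1 >= 1) acc <- acc - a[j] * y[t - j + 1]
    y[t] <- acc / a[1]
  }
  y
}

# forward-backward filtering with the same zero-padding scheme filtfilt uses
bf_filtfilt <- function(b, a, x) {
  pad <- numeric(2 * max(length(a), length(b)))
  y <- bf_iir(b, a, c(x, pad))
  y <- rev(bf_iir(b, a, rev(y)))
  y[seq_along(x)]
}

# brute-force count of voxels whose center lies within radius of the center
bf_sphere_count <- function(center, radius_mm, grid_dim, voxel_size_mm) {
  count <- 0L
  for (x in seq_len(grid_dim[1])) for (y in seq_len(grid_dim[2]))
    for (z in seq_len(grid_dim[3])) {
      d <- sqrt(sum((((c(x, y, z)) - center) * voxel_size_mm)^2))
      if (d <= radius_mm + 1e-9) count <- count + 1L
    }
  count
}

# the full trial-FC pipeline by hand: rest-mean subtraction, OLS residuals via
# normal equations, direct-form zero-phase Butterworth, loop-based Pearson
bf_trial_fc <- function(roi1, roi2, trial_window, rest_window, nuisance,
                        config) {
  rest_idx <- rest_window[1]:rest_window[2]
  x1 <- roi1 - sum(roi1[rest_idx]) / length(rest_idx)
  x2 <- roi2 - sum(roi2[rest_idx]) / length(rest_idx)
  X <- cbind(1, if (is.null(nuisance)) NULL
             else if (inherits(nuisance, "nuisance_set")) nuisance$design
             else nuisance)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  x1 <- x1 - drop(H %*% x1)
  x2 <- x2 - drop(H %*% x2)
  bf <- signal::butter(2, config$online_band / (1 / (2 * config$tr_seconds)),
                       type = "pass")
  x1 <- bf_filtfilt(bf$b, bf$a, x1 - mean(x1))
  x2 <- bf_filtfilt(bf$b, bf$a, x2 - mean(x2))
  idx <- trial_window[1]:trial_window[2]
  bf_pearson(x1[idx], x2[idx])
}

# the offline resting-FC pipeline by hand (regress, scrub, filter, correlate)
bf_resting_fc <- function(roi1, roi2, motion, tissue_means, config) {
  base <- cbind(motion, tissue_means[, c("global", "csf", "gm")])
  X <- cbind(1, base, rbind(0, diff(base)))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  x1 <- roi1 - drop(H %*% roi1)
  x2 <- roi2 - drop(H %*% roi2)
  fd <- bf_fd(motion, config$sphere_head_radius_mm)
  keep <- which(fd <= config$fd_threshold_mm)
  x1 <- x1[keep]; x2 <- x2[keep]
  bf <- signal::butter(2, config$resting_band / (1 / (2 * config$tr_seconds)),
                       type = "pass")
  x1 <- bf_filtfilt(bf$b, bf$a, x1 - mean(x1))
  x2 <- bf_filtfilt(bf$b, bf$a, x2 - mean(x2))
  bf_pearson(x1, x2)
}

# small synthetic cohort change-score frame with an exact linear relation
make_noiseless_changes <- function(n = 10, beta = 20, intercept = -2) {
  fc <- seq(-0.3, 0.2, length.out = n)
  data.frame(participant_id = sprintf("P%02d", seq_len(n)),
             experiment_id = rep(c(1L, 2L), length.out = n),
             horizon = "FCNefDay4",
             delta_rs_fc = fc,
             delta_BDI = intercept + beta * fc,
             delta_RRS_depression = 0, delta_RRS_brooding = 0,
             delta_RRS_reflection = 0, delta_STAI2 = 0,
             stringsAsFactors = FALSE)
}
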