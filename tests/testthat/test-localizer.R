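test_that("design-matrix columns are HRF-convolved boxcars with the right support", {
  des <- design_spec(condition = c("rest", "back2"),
                     onset_s = c(0, 30), duration_s = c(30, 30))
  dm <- build_design_matrix(des, tr_seconds = 1, n_volumes = 80)
  rest_col <- dm$X[, "rest"]
  expect_lt(abs(rest_col[1]), 1e-6)          # nothing before the HRF rises
  expect_gt(max(rest_col[5:35]), 0.5)        # active over the block
  expect_equal(colnames(dm$X)[1], "intercept")

  # linearity of convolution: two blocks equal the sum of shifted singles
  des2 <- design_spec(condition = c("back2", "back2"),
                      onset_s = c(0, 60), duration_s = c(20, 20))
  two <- build_design_matrix(des2, 1, 120)$X[, "back2"]
  one_a <- build_design_matrix(design_spec("back2", 0, 20), 1, 120)$X[, "back2"]
  one_b <- build_design_matrix(design_spec("back2", 60, 20), 1, 120)$X[, "back2"]
  expect_equal(two, one_a + one_b, tolerance = 1e-6)

  expect_error(design_spec("rest", 0, 0), "positive")
  expect_error(design_spec(c("a", "b"), c(0, 10), c(20, 20)), "overlap")
})

test_that("voxel-wise GLM recovers exact coefficients and matches normal equations", {
  set.seed(31)
  des <- design_spec(condition = rep(c("rest", "back2"), 3),
                     onset_s = seq(0, by = 30, length.out = 6),
                     duration_s = rep(30, 6))
  dm <- build_design_matrix(des, 1, 180)
  arr <- array(rnorm(4 * 4 * 4 * 180), c(4, 4, 4, 180))
  # plant a voxel equal to 3x the back2 column
  arr[2, 3, 1, ] <- 3 * dm$X[, "back2"]
  fit <- fit_glm(arr, dm)
  j <- which(fit$colnames == "back2")
  expect_equal(fit$beta[2, 3, 1, j], 3, tolerance = 1e-8)
  expect_lt(fit$sigma2[2, 3, 1], 1e-12)

  # all betas match the brute-force normal-equations solve
  Y <- matrix(arr, 64, 180)
  B_bf <- bf_glm_betas(t(Y), dm$X)
  expect_equal(matrix(fit$beta, 64, ncol(dm$X)), B_bf, tolerance = 1e-6)

  # collinear designs are rejected by name
  Xbad <- cbind(dm$X, dup = dm$X[, "back2"])
  expect_error(fit_glm(arr, Xbad), "dup")
})

test_that("t-contrasts are sign-symmetric and t-distributed under the null", {
  set.seed(32)
  des <- design_spec(condition = rep(c("rest", "back2"), 3),
                     onset_s = seq(0, by = 20, length.out = 6),
                     duration_s = rep(20, 6))
  dm <- build_design_matrix(des, 1, 120)
  arr <- array(rnorm(10 * 10 * 10 * 120), c(10, 10, 10, 120))
  fit <- fit_glm(arr, dm)
  t1 <- t_contrast(fit, c(back2 = 1, rest = -1))
  t2 <- t_contrast(fit, c(back2 = -1, rest = 1))
  expect_equal(as.vector(t1), -as.vector(t2), tolerance = 1e-10)

  ks <- suppressWarnings(
    stats::ks.test(as.vector(t1), stats::pt, df = attr(t1, "dof")))
  expect_gt(ks$p.value, 0.01)

  expect_error(t_contrast(fit, c(back2 = 0)), "zero")
})

test_that("peak search respects the FWE threshold and the minimum cluster size", {
  dims <- c(12, 12, 12)
  mask <- array(TRUE, dims)

  blob <- function(centers, tval) {
    tv <- array(0, dims)
    for (i in seq_len(nrow(centers))) tv[matrix(centers[i, ], 1)] <- tval
    attr(tv, "dof") <- 100
    tv
  }
  # a 12-voxel connected cluster: its max-t voxel is returned
  centers <- as.matrix(expand.grid(x = 4:6, y = 5:6, z = 5:6))  # 12 voxels
  tv <- blob(centers, 8)
  tv[5, 5, 6] <- 9   # unique max inside the cluster
  expect_equal(peak_within_mask(tv, mask), c(5L, 5L, 6L))

  # 9 suprathreshold voxels under a 10-voxel minimum: nothing survives
  tv9 <- blob(as.matrix(expand.grid(x = 4:6, y = 5:7, z = 5)), 8)
  expect_null(peak_within_mask(tv9, mask, min_cluster_voxels = 10))
  expect_equal(peak_within_mask(tv9, mask, min_cluster_voxels = 9)[3], 5L)

  # all-zero map and empty mask
  z <- array(0, dims); attr(z, "dof") <- 100
  expect_null(peak_within_mask(z, mask))
  expect_error(peak_within_mask(tv, array(FALSE, dims)), "empty")

  # peak must lie inside the mask even if larger t exists outside
  m2 <- array(FALSE, dims); m2[1:6, , ] <- TRUE
  tv2 <- blob(centers, 8)
  tv2[10, 10, 10] <- 50  # outside mask, isolated
  expect_equal(peak_within_mask(tv2, m2), c(4L, 5L, 5L))
})

test_that("peak location is equivariant under volume translation", {
  dims <- c(12, 12, 12)
  tv <- array(0, dims)
  cl <- as.matrix(expand.grid(4:6, 4:6, 4:5))
  tv[cl] <- 7; tv[5, 5, 5] <- 8
  attr(tv, "dof") <- 80
  shift <- array(0, dims)
  shift[cl + matrix(rep(c(2, 1, 3), each = nrow(cl)), ncol = 3)] <- 7
  shift[7, 6, 8] <- 8
  attr(shift, "dof") <- 80
  mask <- array(TRUE, dims)
  expect_equal(peak_within_mask(shift, mask),
               peak_within_mask(tv, mask) + c(2L, 1L, 3L))
})

test_that("sphere ROIs match brute-force membership and clip at edges", {
  grid <- c(20L, 20L, 20L)
  roi <- make_sphere_roi(c(10, 10, 10), 8, grid, c(2, 2, 2))
  expect_equal(nrow(roi$voxels),
               bf_sphere_count(c(10, 10, 10), 8, grid, c(2, 2, 2)))
  expect_true(roi$mask[10, 10, 10])
  # all members within radius of center
  d <- sweep(roi$voxels, 2, roi$center, "-") %*% diag(c(2, 2, 2))
  expect_true(all(sqrt(rowSums(d^2)) <= 8 + 1e-9))

  # symmetric under axis permutation on an isotropic grid
  roi_perm <- make_sphere_roi(c(10, 10, 10), 8, grid, c(2, 2, 2))
  vox_sorted <- roi$voxels[order(roi$voxels[, 1], roi$voxels[, 2],
                                 roi$voxels[, 3]), ]
  vox_swapped <- roi_perm$voxels[, c(2, 3, 1)]
  vox_swapped <- vox_swapped[order(vox_swapped[, 1], vox_swapped[, 2],
                                   vox_swapped[, 3]), ]
  expect_equal(unname(vox_sorted), unname(vox_swapped))

  expect_equal(unname(make_sphere_roi(c(3, 3, 3), 0, grid)$voxels),
               matrix(c(3L, 3L, 3L), 1))
  corner <- make_sphere_roi(c(1, 1, 1), 8, grid, c(2, 2, 2))
  expect_true(all(corner$voxels >= 1))
  expect_lt(nrow(corner$voxels), nrow(roi$voxels))
  expect_error(make_sphere_roi(c(0, 5, 5), 8, grid), "outside")
})

test_that("ROI time-series extraction averages member voxels", {
  arr <- array(2.5, c(6, 6, 6, 10))
  roi <- make_sphere_roi(c(3, 3, 3), 4, c(6, 6, 6), c(2, 2, 2))
  expect_equal(extract_roi_timeseries(arr, roi), rep(2.5, 10))

  single <- make_sphere_roi(c(2, 4, 5), 0, c(6, 6, 6))
  set.seed(33)
  arr2 <- array(rnorm(6^3 * 10), c(6, 6, 6, 10))
  expect_equal(extract_roi_timeseries(arr2, single), arr2[2, 4, 5, ])
})

test_that("planted localizer blobs are recovered by their own contrasts only", {
  des <- design_spec(condition = rep(c("rest", "back2"), 4),
                     onset_s = seq(0, by = 40, length.out = 8),
                     duration_s = rep(40, 8))
  run <- simulate_localizer_run(des, list(c(4, 5, 6), c(10, 10, 10)),
                                c("back2", "rest"), effect_size = 5,
                                seed = 7)
  fit <- fit_glm(run$vs, run$design_matrix)
  mask <- array(TRUE, c(14, 14, 14))
  task_peak <- peak_within_mask(t_contrast(fit, c(back2 = 1, rest = -1)), mask)
  dmn_peak <- peak_within_mask(t_contrast(fit, c(rest = 1, back2 = -1)), mask)
  expect_equal(task_peak, c(4L, 5L, 6L))
  expect_equal(dmn_peak, c(10L, 10L, 10L))

  # the ROI series tracks the planted regressor at high SNR
  roi <- make_sphere_roi(task_peak, 4, c(14, 14, 14), c(2, 2, 2))
  ts <- extract_roi_timeseries(run$vs, roi)
  reg <- run$design_matrix$X[, "back2"]
  expect_gt(cor(ts, reg), 0.9)
})
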