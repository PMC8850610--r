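#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking around 6 s minus a scaled
#' gamma undershoot peaking around 16 s, normalised to unit peak.
#'
#' @param t Time points (s) at which to evaluate the HRF.
#' @param peak_delay,undershoot_delay Delays (s) of response and undershoot.
#' @param peak_disp,undershoot_disp Dispersions of the two gammas.
#' @param undershoot_ratio Ratio of undershoot to response amplitude.
#' @return Numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp)
  h[t < 0] <- 0
  if (max(abs(h)) > 0) h <- h / max(h)
  h
}

#' Block design specification
#'
#' @param condition Character vector of block conditions (e.g. \code{"rest"},
#'   \code{"back0"}, \code{"back1"}, \code{"back2"}, \code{"back3"}).
#' @param onset_s,duration_s Numeric vectors of block onsets and durations (s).
#' @return A data frame of class \code{design_spec}, ordered by onset.
#' @export
design_spec <- function(condition, onset_s, duration_s) {
  if (length(condition) != length(onset_s) ||
      length(onset_s) != length(duration_s))
    stop("condition, onset_s and duration_s must have equal length",
         call. = FALSE)
  if (any(onset_s < 0)) stop("onsets must be nonnegative", call. = FALSE)
  if (any(duration_s <= 0))
    stop("block durations must be positive", call. = FALSE)
  o <- order(onset_s)
  d <- data.frame(condition = as.character(condition)[o],
                  onset_s = onset_s[o], duration_s = duration_s[o],
                  stringsAsFactors = FALSE)
  ends <- d$onset_s + d$duration_s
  if (any(d$onset_s[-1] < ends[-nrow(d)] - 1e-9))
    stop("blocks overlap", call. = FALSE)
  class(d) <- c("design_spec", class(d))
  d
}

#' Build a block-design GLM design matrix
#'
#' Each modeled condition becomes a boxcar (1 during that condition's blocks,
#' from onset to offset) convolved with the canonical double-gamma HRF and
#' sampled at the TR. Motion parameters, when given, are appended as
#' regressors of no interest. Conditions can optionally be sequentially
#' orthogonalized (each column has the preceding condition columns projected
#' out, in the order given).
#'
#' @param design A \code{\link{design_spec}}.
#' @param tr_seconds Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param conditions Conditions to model; defaults to all in the design.
#' @param motion Optional motion-parameter matrix appended as confounds.
#' @param orthogonalize Sequentially orthogonalize condition columns.
#' @return A list of class \code{glm_design}: \code{X} (time x regressor,
#'   including intercept), \code{conditions} (names of condition columns).
#' @export
build_design_matrix <- function(design, tr_seconds, n_volumes,
                                conditions = NULL, motion = NULL,
                                orthogonalize = FALSE) {
  stopifnot(inherits(design, "design_spec"))
  if (max(design$onset_s + design$duration_s) > n_volumes * tr_seconds + 1e-9)
    stop("design extends beyond the scanned volumes", call. = FALSE)
  if (is.null(conditions)) conditions <- unique(design$condition)
  dt <- 0.1  # HRF convolution grid (s)
  n_fine <- ceiling(n_volumes * tr_seconds / dt)
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  cols <- matrix(0, n_volumes, length(conditions))
  colnames(cols) <- conditions
  for (j in seq_along(conditions)) {
    box <- numeric(n_fine)
    blk <- design[design$condition == conditions[j], , drop = FALSE]
    if (nrow(blk) == 0L)
      stop("condition not present in design: ", conditions[j], call. = FALSE)
    for (b in seq_len(nrow(blk))) {
      i0 <- floor(blk$onset_s[b] / dt) + 1
      i1 <- min(n_fine, ceiling((blk$onset_s[b] + blk$duration_s[b]) / dt))
      box[i0:i1] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt
    sample_idx <- pmin(n_fine, round((seq_len(n_volumes) - 1) * tr_seconds / dt) + 1)
    cols[, j] <- conv[sample_idx]
  }
  if (orthogonalize && length(conditions) > 1L) {
    for (j in 2:ncol(cols)) {
      prev <- cbind(1, cols[, 1:(j - 1), drop = FALSE])
      cols[, j] <- qr.resid(qr(prev), cols[, j])
    }
  }
  X <- cbind(intercept = 1, cols)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes)
      stop("motion rows must equal n_volumes", call. = FALSE)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }
  structure(list(X = X, conditions = conditions), class = "glm_design")
}

#' Fit a voxel-wise GLM
#'
#' Ordinary least squares of every voxel's time series on the design matrix.
#'
#' @param vs A \code{\link{volume_series}} (or 4D array).
#' @param design A \code{glm_design} from \code{\link{build_design_matrix}}
#'   or a bare design matrix (an intercept is NOT added automatically in that
#'   case).
#' @return A list of class \code{glm_fit}: \code{beta} (4D array,
#'   x,y,z,regressor), \code{sigma2} (3D residual variance), \code{dof},
#'   \code{XtXinv}, \code{colnames}.
#' @export
fit_glm <- function(vs, design) {
  arr <- if (inherits(vs, "volume_series")) vs$data else vs
  dims <- dim(arr)
  X <- if (inherits(design, "glm_design")) design$X else as.matrix(design)
  n <- dims[4]
  if (nrow(X) != n)
    stop("design rows (", nrow(X), ") must equal number of volumes (", n, ")",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  Y <- matrix(arr, prod(dims[1:3]), n)        # voxels x time
  B <- t(qr.coef(qrX, t(Y)))                  # voxels x p
  resid <- t(qr.resid(qrX, t(Y)))
  dof <- n - ncol(X)
  sigma2 <- rowSums(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  structure(list(beta = array(B, c(dims[1:3], ncol(X))),
                 sigma2 = array(sigma2, dims[1:3]),
                 dof = dof,
                 XtXinv = XtXinv,
                 colnames = colnames(X)),
            class = "glm_fit")
}

#' Voxel-wise t-contrast
#'
#' Computes \eqn{t = c'b / sqrt(s^2 c'(X'X)^{-1}c)} at every voxel.
#'
#' @param glm A \code{glm_fit} from \code{\link{fit_glm}}.
#' @param contrast Named numeric vector of weights over design columns (names
#'   must match design column names; unnamed full-length vectors also
#'   accepted). At least one weight must be nonzero.
#' @return A 3D array of t statistics with attribute \code{dof}.
#' @export
t_contrast <- function(glm, contrast) {
  stopifnot(inherits(glm, "glm_fit"))
  p <- length(glm$colnames)
  c_full <- numeric(p)
  if (!is.null(names(contrast)) && any(nzchar(names(contrast)))) {
    unknown <- setdiff(names(contrast), glm$colnames)
    if (length(unknown))
      stop("contrast names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    c_full[match(names(contrast), glm$colnames)] <- contrast
  } else {
    if (length(contrast) != p)
      stop("unnamed contrast must have length ", p, call. = FALSE)
    c_full <- as.numeric(contrast)
  }
  if (all(c_full == 0)) stop("contrast is all zero", call. = FALSE)
  dims3 <- dim(glm$sigma2)
  B <- matrix(glm$beta, prod(dims3), p)
  eff <- drop(B %*% c_full)
  cvc <- drop(t(c_full) %*% glm$XtXinv %*% c_full)
  tval <- eff / sqrt(as.vector(glm$sigma2) * cvc)
  tval[!is.finite(tval)] <- 0
  structure(array(tval, dims3), dof = glm$dof)
}

# 18-connected components of a logical 3D array (faces + edges)
label_components <- function(mask3d) {
  dims <- dim(mask3d)
  labels <- array(0L, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) %in% c(1, 2), , drop = FALSE]
  current <- 0L
  idx_all <- which(mask3d)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      nb <- sweep(offsets, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[mask3d[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- current
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Thresholded peak within an anatomical mask
#'
#' Thresholds a t map at a family-wise-error-corrected level (Bonferroni over
#' in-mask voxels), keeps only suprathreshold voxels belonging to connected
#' components (18-neighbour connectivity) of at least
#' \code{min_cluster_voxels}, and returns the maximum-t voxel among the
#' survivors inside the mask. Ties are broken by the lowest linear voxel index
#' in scan order.
#'
#' @param t_volume 3D t-statistic array with a \code{dof} attribute (or pass
#'   \code{dof}).
#' @param mask Logical/0-1 3D array of the same shape; the search region.
#' @param alpha_fwe Family-wise error level (default 0.05).
#' @param min_cluster_voxels Minimum surviving cluster size (default 10).
#' @param dof Degrees of freedom; defaults to \code{attr(t_volume, "dof")}.
#' @return Integer vector (x, y, z) of the peak voxel (1-based), or \code{NULL}
#'   if nothing survives.
#' @export
peak_within_mask <- function(t_volume, mask, alpha_fwe = 0.05,
                             min_cluster_voxels = 10,
                             dof = attr(t_volume, "dof")) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (!all(dim(mask) == dim(t_volume)))
    stop("mask and t volume dimensions differ", call. = FALSE)
  if (is.null(dof)) stop("degrees of freedom unknown; pass dof", call. = FALSE)
  n_mask <- sum(mask)
  thresh <- qt(1 - alpha_fwe / n_mask, df = dof, lower.tail = TRUE)
  supra <- (t_volume > thresh) & mask
  if (!any(supra)) return(NULL)
  labs <- label_components(supra)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_cluster_voxels)
  if (!length(keep)) return(NULL)
  survivors <- which(array(labs %in% keep, dim(labs)) & supra)
  best <- survivors[which.max(t_volume[survivors])]  # which.max -> first/lowest index on ties
  as.integer(arrayInd(best, dim(t_volume)))
}

#' Build a spherical ROI around a peak voxel
#'
#' Membership is every voxel whose center lies within \code{radius_mm}
#' (Euclidean, in mm) of the center voxel's center; the sphere is clipped at
#' the grid edges.
#'
#' @param center Integer (x, y, z) voxel coordinate (1-based).
#' @param radius_mm Sphere radius in mm.
#' @param grid_dim Integer length-3 grid dimensions.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return A list of class \code{roi_sphere}: \code{center}, \code{center_mm},
#'   \code{radius_mm}, \code{voxels} (n x 3 integer matrix), \code{mask}
#'   (logical 3D array).
#' @export
make_sphere_roi <- function(center, radius_mm, grid_dim,
                            voxel_size_mm = c(2, 2, 2)) {
  center <- as.integer(center)
  grid_dim <- as.integer(grid_dim)
  if (radius_mm < 0) stop("radius_mm must be nonnegative", call. = FALSE)
  if (any(center < 1L) || any(center > grid_dim))
    stop("center outside grid", call. = FALSE)
  half <- ceiling(radius_mm / voxel_size_mm)
  rng <- function(a) max(1L, center[a] - half[min(a, length(half))]):
    min(grid_dim[a], center[a] + half[min(a, length(half))])
  cand <- as.matrix(expand.grid(x = rng(1), y = rng(2), z = rng(3)))
  dmm <- sweep(cand, 2, center, "-")
  dmm <- sweep(dmm, 2, voxel_size_mm, "*")
  inside <- sqrt(rowSums(dmm^2)) <= radius_mm + 1e-9
  voxels <- cand[inside, , drop = FALSE]
  mask <- array(FALSE, grid_dim)
  mask[voxels] <- TRUE
  structure(list(center = center,
                 center_mm = center * voxel_size_mm,
                 radius_mm = radius_mm,
                 voxels = voxels,
                 mask = mask),
            class = "roi_sphere")
}

#' @export
print.roi_sphere <- function(x, ...) {
  cat(sprintf("Sphere ROI: center (%s) voxel, radius %g mm, %d member voxels\n",
              paste(x$center, collapse = ", "), x$radius_mm, nrow(x$voxels)))
  invisible(x)
}

#' Mean time series over an ROI
#'
#' @param vs A \code{\link{volume_series}} or 4D array.
#' @param roi A \code{roi_sphere} (or a logical 3D mask).
#' @return Numeric vector: per-volume mean over member voxels.
#' @export
extract_roi_timeseries <- function(vs, roi) {
  arr <- if (inherits(vs, "volume_series")) vs$data else vs
  mask <- if (inherits(roi, "roi_sphere")) roi$mask else array(as.logical(roi), dim(roi))
  if (!all(dim(mask) == dim(arr)[1:3]))
    stop("ROI grid does not match the volume grid", call. = FALSE)
  if (!any(mask)) stop("ROI is empty", call. = FALSE)
  n <- dim(arr)[4]
  Y <- matrix(arr, ncol = n)
  colMeans(Y[which(mask), , drop = FALSE])
}
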