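#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of the absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc length on a sphere of radius \code{head_radius_mm}.
#' The first frame has FD 0 by convention.
#'
#' @param motion Numeric matrix, one row per volume, columns
#'   \code{tx, ty, tz} (mm) then \code{rx, ry, rz} (radians).
#' @param head_radius_mm Head radius used for the rotation terms (mm).
#' @return Numeric vector of per-volume FD in mm.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  if (!is.matrix(motion)) motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns", call. = FALSE)
  if (nrow(motion) < 1L) stop("motion must have at least one row", call. = FALSE)
  if (any(!is.finite(motion)))
    stop("motion parameters must be finite", call. = FALSE)
  d <- diff(motion)
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]))
  c(0, fd)
}

#' Build the nuisance regressor set
#'
#' Assembles the denoising design: six motion parameters, whole-brain (global),
#' CSF and grey-matter mean signals, optionally the backward-difference
#' derivatives of all nine, and one unit indicator column per motion-spike
#' volume (frames whose framewise displacement exceeds the threshold).
#'
#' @param motion Numeric matrix of 6 motion parameters (rows = volumes).
#' @param tissue_means Numeric matrix or data frame with columns
#'   \code{global}, \code{csf}, \code{gm} (rows = volumes).
#' @param include_derivatives Add backward-difference derivatives (first
#'   element 0) of the nine base regressors.
#' @param spike_volumes Integer vector of 1-based volume indices to receive
#'   unit spike indicator columns (may be empty).
#' @return A list of class \code{nuisance_set} with elements \code{design}
#'   (time x regressor matrix) and \code{labels}.
#' @export
build_nuisance <- function(motion, tissue_means, include_derivatives = TRUE,
                           spike_volumes = integer(0)) {
  motion <- as.matrix(motion)
  tissue_means <- as.matrix(tissue_means)
  if (ncol(motion) != 6L) stop("motion must have 6 columns", call. = FALSE)
  if (!all(c("global", "csf", "gm") %in% colnames(tissue_means)))
    stop("tissue_means needs columns global, csf, gm", call. = FALSE)
  n <- nrow(motion)
  if (nrow(tissue_means) != n)
    stop("motion and tissue_means must have the same number of rows",
         call. = FALSE)
  base <- cbind(motion, tissue_means[, c("global", "csf", "gm")])
  labels <- c("tx", "ty", "tz", "rx", "ry", "rz", "global", "csf", "gm")
  design <- base
  if (include_derivatives) {
    deriv <- rbind(0, diff(base))
    design <- cbind(design, deriv)
    labels <- c(labels, paste0("d_", labels))
  }
  spike_volumes <- as.integer(spike_volumes)
  if (length(spike_volumes)) {
    if (any(spike_volumes < 1L | spike_volumes > n))
      stop("spike_volumes out of range", call. = FALSE)
    spikes <- matrix(0, n, length(spike_volumes))
    spikes[cbind(spike_volumes, seq_along(spike_volumes))] <- 1
    design <- cbind(design, spikes)
    labels <- c(labels, paste0("spike_", spike_volumes))
  }
  colnames(design) <- labels
  structure(list(design = design, labels = labels), class = "nuisance_set")
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary least squares of the signal on the nuisance design (an intercept
#' is always included) returning the residual. If the design is rank
#' deficient, a warning is issued and a pivoted QR (pseudo-inverse) fit is
#' used, which still leaves residuals orthogonal to the retained column space.
#'
#' @param signal Numeric vector or time x k matrix of signals.
#' @param nuisance A \code{nuisance_set} from \code{\link{build_nuisance}}, or
#'   a plain design matrix, or \code{NULL} (demean only).
#' @return Residual signal with the same shape as \code{signal}.
#' @export
regress_out <- function(signal, nuisance = NULL) {
  sig <- as.matrix(signal)
  n <- nrow(sig)
  X <- if (is.null(nuisance)) matrix(1, n, 1)
       else cbind(1, if (inherits(nuisance, "nuisance_set")) nuisance$design
                     else as.matrix(nuisance))
  if (nrow(X) != n)
    stop("nuisance design rows (", nrow(X), ") must match signal length (",
         n, ")", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("nuisance design is rank deficient (rank ", qrX$rank, " < ",
            ncol(X), " columns); using a pivoted least-squares fit")
  res <- qr.resid(qrX, sig)
  if (is.vector(signal)) drop(res) else res
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion. The pass band must
#' lie strictly inside (0, Nyquist). The DC component is removed by the
#' high-pass edge; the series is demeaned before filtering to minimise edge
#' transients and the mean is not restored.
#'
#' @param x Numeric vector or time x k matrix.
#' @param tr_seconds Sampling interval (s).
#' @param low_hz,high_hz Pass-band edges (Hz).
#' @param order Butterworth order of the underlying low/high sections.
#' @return Filtered signal, same shape as \code{x}.
#' @export
bandpass <- function(x, tr_seconds, low_hz, high_hz, order = 2) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("need 0 < low < high < Nyquist (", signif(nyq, 4), " Hz)",
         call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  apply_filter <- function(v) {
    v <- v - mean(v)
    signal::filtfilt(bf, v)
  }
  if (is.matrix(x)) apply(x, 2, apply_filter) else apply_filter(as.numeric(x))
}

#' Censor high-motion frames from a time series
#'
#' Removes exactly the frames whose framewise displacement exceeds the
#' threshold, preserving the order of the survivors.
#'
#' @param series Numeric vector or time x k matrix.
#' @param fd Per-frame framewise displacement (mm), same length as the series.
#' @param threshold_mm Censoring threshold (mm).
#' @return A list with \code{series} (censored) and \code{kept}
#'   (1-based indices of surviving frames).
#' @export
scrub <- function(series, fd, threshold_mm = 0.5) {
  s <- as.matrix(series)
  if (length(fd) != nrow(s))
    stop("fd length must match series length", call. = FALSE)
  kept <- which(fd <= threshold_mm)
  if (length(kept) == 0L)
    stop("scrubbing removed every frame (threshold ", threshold_mm, " mm)",
         call. = FALSE)
  out <- s[kept, , drop = FALSE]
  list(series = if (is.vector(series)) drop(out) else out, kept = kept)
}

# 1D Gaussian kernel, sigma in samples, support +/- 4 sigma
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# reflective-boundary 1D convolution along the first axis of a matrix
convolve_axis <- function(m, kernel) {
  half <- (length(kernel) - 1L) / 2L
  if (half == 0L) return(m)
  n <- nrow(m)
  front <- rev(seq_len(min(half, n)))              # m[half], ..., m[1]
  back <- seq(n, by = -1L, length.out = min(half, n))  # m[n], m[n-1], ...
  idx <- c(front, seq_len(n), back)
  # if kernel wider than data, clamp the reflection at the edges
  while (length(idx) < n + 2 * half) idx <- c(idx[1], idx, idx[length(idx)])
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

#' Spatial Gaussian smoothing of a volume series
#'
#' Per-volume separable 3D Gaussian convolution with reflective boundaries.
#' The kernel sigma per axis is \code{FWHM / (2 sqrt(2 log 2)) / voxel_size}.
#' A FWHM of 0 returns the input unchanged.
#'
#' @param vs A \code{\link{volume_series}} or a 3D/4D array (then
#'   \code{voxel_size_mm} is required).
#' @param fwhm_mm Full width at half maximum of the Gaussian (mm).
#' @param voxel_size_mm Voxel size, used when \code{vs} is a bare array.
#' @return Smoothed object of the same type as the input.
#' @export
gaussian_smooth <- function(vs, fwhm_mm, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative", call. = FALSE)
  is_vs <- inherits(vs, "volume_series")
  arr <- if (is_vs) vs$data else vs
  vox <- if (is_vs) vs$voxel_size_mm else voxel_size_mm
  if (is.null(vox)) stop("voxel_size_mm required for bare arrays", call. = FALSE)
  if (fwhm_mm == 0) return(vs)
  dims <- dim(arr)
  if (length(dims) == 3L) { arr <- array(arr, c(dims, 1L)); dims <- dim(arr) }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  kernels <- lapply(sigma_vox, gaussian_kernel)
  out <- arr
  for (t in seq_len(dims[4])) {
    v <- array(out[, , , t], dims[1:3])
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      vp <- aperm(v, perm)
      d <- dim(vp)
      vp <- array(convolve_axis(matrix(vp, d[1]), kernels[[ax]]), d)
      v <- aperm(vp, order(perm))
    }
    out[, , , t] <- v
  }
  if (length(dim(vs)) == 3L && !is_vs) out <- out[, , , 1]
  if (is_vs) { vs$data <- out; vs } else out
}
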