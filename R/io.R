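#' @importFrom stats coef cor fitted lm logLik pchisq predict qt residuals rnorm sd var
#' @importFrom utils read.table write.table write.csv read.csv
NULL

# fixed vocabulary for cohort day labels
DAY_LEVELS <- c("Day0", "FCNefDay1", "FCNefDay2", "FCNefDay3", "FCNefDay4",
                "Post1m", "Post2m")

#' Construct a 4D BOLD volume series
#'
#' A thin container for a 4D array of BOLD data plus the metadata the pipeline
#' needs: repetition time, voxel size, the voxel-to-mm affine, and how many
#' leading (steady-state) volumes were discarded before the array begins.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-mm transform; defaults to a diagonal scaling by
#'   the voxel size (0-based voxel indices).
#' @param n_discarded_leading Number of leading volumes already dropped.
#' @return An object of class \code{volume_series}.
#' @export
volume_series <- function(data, tr_seconds, voxel_size_mm = c(2, 2, 2),
                          affine = NULL, n_discarded_leading = 0L) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 1L) stop("need at least one volume", call. = FALSE)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be positive", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive numbers", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data,
                 tr_seconds = tr_seconds,
                 voxel_size_mm = voxel_size_mm,
                 affine = affine,
                 n_discarded_leading = as.integer(n_discarded_leading)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD volume series: %d x %d x %d voxels, %d volumes (TR %g s)\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  cat(sprintf("  voxel size %s mm; %d leading volume(s) discarded\n",
              paste(x$voxel_size_mm, collapse = " x "), x$n_discarded_leading))
  invisible(x)
}

#' Read a 4D NIfTI file as a volume series
#'
#' Reads a NIfTI-1 file, takes the TR from the header's fourth pixdim (unless
#' overridden), and drops the leading steady-state volumes given by
#' \code{config$steady_state_discard_volumes}, recording the count in the
#' returned object.
#'
#' @param path Path to a NIfTI-1 file holding a 4D image.
#' @param config An \code{\link{fcnef_config}}; controls the leading-volume
#'   discard.
#' @param tr_seconds Optional TR override when the header pixdim is absent or
#'   zero.
#' @return A \code{\link{volume_series}}.
#' @export
read_volume_series <- function(path, config = fcnef_config(), tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 4L)
    stop("expected a 4D NIfTI image, got ", length(dims), "D", call. = FALSE)
  pix <- RNifti::pixdim(img)
  tr <- if (!is.null(tr_seconds)) tr_seconds
        else if (length(pix) >= 4L && pix[4] > 0) pix[4]
        else config$tr_seconds
  n_discard <- config$steady_state_discard_volumes
  if (dims[4] <= n_discard)
    stop("series has ", dims[4], " volumes; cannot discard ", n_discard,
         call. = FALSE)
  arr <- as.array(img)
  if (n_discard > 0L) arr <- arr[, , , -(seq_len(n_discard)), drop = FALSE]
  volume_series(arr,
                tr_seconds = tr,
                voxel_size_mm = pix[1:3],
                affine = structure(RNifti::xform(img), dimnames = NULL),
                n_discarded_leading = n_discard)
}

#' Write a volume series to a NIfTI-1 file
#'
#' @param vs A \code{\link{volume_series}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume_series <- function(vs, path) {
  stopifnot(inherits(vs, "volume_series"))
  img <- RNifti::asNifti(vs$data)
  RNifti::pixdim(img) <- c(vs$voxel_size_mm, vs$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read rigid-body motion parameters
#'
#' Expects a whitespace- or tab-delimited numeric file with six columns per
#' volume: three translations in mm followed by three rotations (the SPM
#' \code{rp_*.txt} column order). Rotations are stored in radians; set
#' \code{rotations = "degrees"} if the file records degrees.
#'
#' @param path Path to the 6-column file.
#' @param rotations Unit of the rotation columns in the file.
#' @return A numeric matrix with one row per volume and columns
#'   \code{tx, ty, tz, rx, ry, rz} (translations mm, rotations radians).
#' @export
read_motion_params <- function(path, rotations = c("radians", "degrees")) {
  rotations <- match.arg(rotations)
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion parameter file must have 6 columns, found ", ncol(m),
         call. = FALSE)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("motion parameters must be finite numbers", call. = FALSE)
  if (rotations == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write motion parameters to a tab-separated file
#'
#' @param motion Numeric matrix with 6 columns (translations mm, rotations
#'   radians).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_motion_params <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  write.table(motion, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort questionnaire table
#'
#' Reads the long-format participant-by-day table used by the group analyses:
#' one row per participant and day, with total questionnaire scores and the
#' resting-state functional connectivity measured that day.
#'
#' Expected columns: \code{participant_id}, \code{experiment_id} (1 or 2),
#' \code{day} (one of \code{Day0}, \code{FCNefDay1}..\code{FCNefDay4},
#' \code{Post1m}, \code{Post2m}), \code{BDI}, \code{RRS_depression},
#' \code{RRS_brooding}, \code{RRS_reflection}, \code{STAI2}, \code{rs_fc}.
#'
#' @param path CSV path.
#' @return A validated data frame of class \code{c("cohort_table", "data.frame")}.
#' @export
read_cohort_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df A data frame with the columns documented in
#'   \code{\link{read_cohort_table}}.
#' @return The validated table with class \code{cohort_table} prepended.
#' @export
as_cohort_table <- function(df) {
  required <- c("participant_id", "experiment_id", "day", "BDI",
                "RRS_depression", "RRS_brooding", "RRS_reflection",
                "STAI2", "rs_fc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$experiment_id %in% c(1L, 2L)))
    stop("experiment_id must be 1 or 2", call. = FALSE)
  bad_days <- setdiff(unique(df$day), DAY_LEVELS)
  if (length(bad_days))
    stop("unknown day label(s): ", paste(bad_days, collapse = ", "),
         "; allowed: ", paste(DAY_LEVELS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$rs_fc)) || any(df$rs_fc < -1 | df$rs_fc > 1))
    stop("rs_fc must lie in [-1, 1]", call. = FALSE)
  key <- paste(df$participant_id, df$day)
  if (anyDuplicated(key))
    stop("duplicate (participant, day) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (!inherits(df, "cohort_table")) class(df) <- c("cohort_table", class(df))
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  as_cohort_table(as.data.frame(cohort))
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
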