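# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Signal specification for synthetic two-ROI BOLD data
#'
#' Describes the generative model for a synthetic ROI pair: two unit-variance
#' Gaussian AR(1) processes whose innovations are correlated at
#' \code{target_r} (via the Cholesky factor of the 2x2 target correlation),
#' so the stationary cross-correlation of the pair equals \code{target_r}.
#' Optional additive structure emulates what real BOLD carries on top:
#' shared global/CSF/grey-matter nuisance signals, slow drift, independent
#' measurement noise (which attenuates the observable correlation), and
#' head-motion spikes implemented as sustained translation steps large enough
#' to exceed the 0.5 mm framewise-displacement threshold at exactly the
#' requested frames.
#'
#' @param target_r Planted Pearson correlation of the latent pair, |r| < 1.
#' @param noise_sd SD of independent measurement noise added to each ROI.
#' @param drift_amplitude Amplitude of a slow (linear + sinusoidal) scanner
#'   drift carried inside the global signal (it reaches the ROIs through the
#'   \code{global} nuisance amplitude, as scanner drift does in real data).
#' @param nuisance_amplitudes Named numeric: amplitudes of the shared
#'   \code{global}, \code{csf}, \code{gm} components added to both ROIs.
#' @param spike_volumes 1-based frame indices receiving motion spikes.
#' @param autocorrelation AR(1) coefficient of the latent processes, in [0, 1).
#' @return A list of class \code{signal_spec}.
#' @export
signal_spec <- function(target_r = -0.1, noise_sd = 0, drift_amplitude = 0,
                        nuisance_amplitudes = c(global = 0, csf = 0, gm = 0),
                        spike_volumes = integer(0),
                        autocorrelation = 0.3) {
  if (!is.finite(target_r) || abs(target_r) >= 1)
    stop("target_r must satisfy |target_r| < 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (autocorrelation < 0 || autocorrelation >= 1)
    stop("autocorrelation must be in [0, 1)", call. = FALSE)
  amps <- c(global = 0, csf = 0, gm = 0)
  amps[names(nuisance_amplitudes)] <- nuisance_amplitudes
  structure(list(target_r = target_r, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 nuisance_amplitudes = amps,
                 spike_volumes = as.integer(spike_volumes),
                 autocorrelation = autocorrelation),
            class = "signal_spec")
}

# unit-variance AR(1) series driven by given innovations (scaled internally)
ar1_series <- function(innov, phi) {
  n <- length(innov)
  innov <- innov * sqrt(1 - phi^2)
  s <- numeric(n)
  s[1] <- innov[1] / sqrt(1 - phi^2)  # stationary start
  for (t in 2:n) s[t] <- phi * s[t - 1] + innov[t]
  s
}

# correlated bivariate AR(1) pair; rho may vary per frame
latent_pair <- function(n, rho, phi) {
  if (length(rho) == 1L) rho <- rep(rho, n)
  z1 <- rnorm(n); z2 <- rnorm(n)
  e1 <- z1
  e2 <- rho * z1 + sqrt(1 - rho^2) * z2
  cbind(ar1_series(e1, phi), ar1_series(e2, phi))
}

# small-jitter motion trace with sustained translation steps at spike frames
simulate_motion <- function(n, spike_volumes = integer(0),
                            spike_step_mm = 0.6, jitter_sd_mm = 0.01,
                            jitter_sd_rad = 1e-4) {
  m <- cbind(matrix(rnorm(3 * n, sd = jitter_sd_mm), n, 3),
             matrix(rnorm(3 * n, sd = jitter_sd_rad), n, 3))
  m <- apply(m, 2, cumsum)  # random-walk motion, tiny steps
  for (k in spike_volumes) {
    if (k >= 1 && k <= n) m[k:n, 1] <- m[k:n, 1] + spike_step_mm
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate a two-ROI BOLD pair with planted correlation
#'
#' Generates the full input bundle for the connectivity pipelines: two ROI
#' time series whose latent correlation is \code{spec$target_r}, a motion
#' trace whose framewise displacement exceeds 0.5 mm at exactly
#' \code{spec$spike_volumes}, and global/CSF/grey-matter nuisance series
#' (always returned; added to the ROI signals with the amplitudes in the
#' spec).
#'
#' @param n_volumes Number of volumes (at least 10).
#' @param spec A \code{\link{signal_spec}}.
#' @param seed Integer seed; generation is reproducible per seed.
#' @return A list with \code{roi1}, \code{roi2} (numeric vectors),
#'   \code{motion} (n x 6), \code{tissue_means} (n x 3, columns
#'   \code{global, csf, gm}), and \code{spec}.
#' @export
simulate_roi_pair <- function(n_volumes, spec = signal_spec(), seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"))
  if (n_volumes < 10L) stop("n_volumes must be at least 10", call. = FALSE)
  with_seed(seed, {
    lat <- latent_pair(n_volumes, spec$target_r, spec$autocorrelation)
    tissue <- sapply(1:3, function(i) ar1_series(rnorm(n_volumes), 0.9))
    colnames(tissue) <- c("global", "csf", "gm")
    # scanner drift is a whole-brain phenomenon: it lives inside the global
    # signal and reaches the ROIs through the global amplitude, so
    # global-signal regression can remove it the way it does in real data
    tt <- seq_len(n_volumes) / n_volumes
    tissue[, "global"] <- tissue[, "global"] +
      spec$drift_amplitude * (tt + 0.5 * sin(2 * pi * tt))
    shared <- drop(tissue %*% spec$nuisance_amplitudes)
    roi1 <- lat[, 1] + shared + rnorm(n_volumes, sd = spec$noise_sd)
    roi2 <- lat[, 2] + shared + rnorm(n_volumes, sd = spec$noise_sd)
    motion <- simulate_motion(n_volumes, spec$spike_volumes)
    list(roi1 = roi1, roi2 = roi2, motion = motion, tissue_means = tissue,
         spec = spec)
  })
}

#' Simulate a full neurofeedback session
#'
#' Generates a session laid out by a \code{\link{trial_schedule}}: ROI signals
#' whose latent correlation equals \code{per_trial_target_r[i]} during trial
#' i's induction period (and \code{spec$target_r} elsewhere), plus motion,
#' tissue nuisance series, the assembled nuisance design (with derivatives
#' and FD spike regressors per the online pipeline), and the session
#' segmentation.
#'
#' @param schedule A \code{\link{trial_schedule}}.
#' @param per_trial_target_r Numeric vector, one planted correlation per
#'   trial.
#' @param spec A \code{\link{signal_spec}} for the non-induction background
#'   and nuisance structure.
#' @param seed Integer seed.
#' @param config An \code{\link{fcnef_config}} (TR, FD threshold, bands).
#' @return A session bundle: list with \code{roi1}, \code{roi2},
#'   \code{motion}, \code{tissue_means}, \code{fd}, \code{nuisance}
#'   (a \code{nuisance_set}), \code{segments} (a \code{segment_index}),
#'   \code{schedule}, \code{truth} (per-trial planted correlations).
#' @export
simulate_session <- function(schedule = trial_schedule(),
                             per_trial_target_r,
                             spec = signal_spec(), seed = 1L,
                             config = fcnef_config()) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (length(per_trial_target_r) != schedule$n_trials)
    stop("per_trial_target_r must have one entry per trial (",
         schedule$n_trials, ")", call. = FALSE)
  if (any(abs(per_trial_target_r) >= 1))
    stop("per-trial target correlations must satisfy |r| < 1", call. = FALSE)
  tr <- config$tr_seconds
  n_volumes <- floor(schedule_duration(schedule) / tr)
  seg <- segment_session(schedule, tr, n_volumes)
  rho <- rep(spec$target_r, n_volumes)
  for (i in seq_len(nrow(seg$trials))) {
    # plant over the whole induction period incl. the hemodynamic discard
    start <- seg$trials$induction_used_start[i] -
      floor(schedule$hemodynamic_discard_seconds / tr)
    idx <- max(1L, start):seg$trials$induction_used_end[i]
    rho[idx] <- per_trial_target_r[i]
  }
  with_seed(seed, {
    lat <- latent_pair(n_volumes, rho, spec$autocorrelation)
    tissue <- sapply(1:3, function(i) ar1_series(rnorm(n_volumes), 0.9))
    colnames(tissue) <- c("global", "csf", "gm")
    tt <- seq_len(n_volumes) / n_volumes
    tissue[, "global"] <- tissue[, "global"] +
      spec$drift_amplitude * (tt + 0.5 * sin(2 * pi * tt))
    shared <- drop(tissue %*% spec$nuisance_amplitudes)
    roi1 <- lat[, 1] + shared + rnorm(n_volumes, sd = spec$noise_sd)
    roi2 <- lat[, 2] + shared + rnorm(n_volumes, sd = spec$noise_sd)
    motion <- simulate_motion(n_volumes, spec$spike_volumes)
    fd <- compute_fd(motion, config$sphere_head_radius_mm)
    spikes <- which(fd > config$fd_threshold_mm)
    nuis <- build_nuisance(motion, tissue, include_derivatives = TRUE,
                           spike_volumes = spikes)
    list(roi1 = roi1, roi2 = roi2, motion = motion, tissue_means = tissue,
         fd = fd, nuisance = nuis, segments = seg, schedule = schedule,
         truth = list(per_trial_target_r = per_trial_target_r))
  })
}

#' Simulate a block-design localizer run with planted activation blobs
#'
#' Builds a small 4D volume series in which spherical blobs respond to chosen
#' conditions of a block design: voxels inside each blob carry that
#' condition's boxcar-convolved-with-HRF regressor scaled by
#' \code{effect_size}, on top of unit white noise; all other voxels are pure
#' noise.
#'
#' @param design A \code{\link{design_spec}}.
#' @param blob_centers List of integer (x, y, z) voxel coordinates.
#' @param blob_conditions Character vector, the design condition each blob
#'   responds to (recycled if length 1).
#' @param effect_size Signal amplitude per unit regressor (in noise SD units).
#' @param seed Integer seed.
#' @param grid_dim Grid dimensions (default 14 x 14 x 14).
#' @param voxel_size_mm Voxel size (default 2 mm isotropic).
#' @param blob_radius_mm Blob radius (default 4 mm).
#' @param tr_seconds Repetition time.
#' @return A list with \code{vs} (a \code{\link{volume_series}}),
#'   \code{design}, \code{blobs} (list of \code{roi_sphere}),
#'   \code{conditions} (per-blob condition), and \code{truth} (blob centers).
#' @export
simulate_localizer_run <- function(design, blob_centers, blob_conditions,
                                   effect_size = 3, seed = 1L,
                                   grid_dim = c(14L, 14L, 14L),
                                   voxel_size_mm = c(2, 2, 2),
                                   blob_radius_mm = 4,
                                   tr_seconds = 1) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.list(blob_centers)) blob_centers <- list(blob_centers)
  blob_conditions <- rep_len(as.character(blob_conditions),
                             length(blob_centers))
  bad <- setdiff(blob_conditions, unique(design$condition))
  if (length(bad))
    stop("blob condition(s) not in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (ctr in blob_centers) {
    if (any(ctr < 1L) || any(ctr > grid_dim))
      stop("blob center outside grid", call. = FALSE)
  }
  n_volumes <- ceiling(max(design$onset_s + design$duration_s) / tr_seconds)
  dm <- build_design_matrix(design, tr_seconds, n_volumes)
  with_seed(seed, {
    arr <- array(rnorm(prod(grid_dim) * n_volumes),
                 c(grid_dim, n_volumes))
    blobs <- vector("list", length(blob_centers))
    for (b in seq_along(blob_centers)) {
      blobs[[b]] <- make_sphere_roi(blob_centers[[b]], blob_radius_mm,
                                    grid_dim, voxel_size_mm)
      reg <- dm$X[, blob_conditions[b]]
      reg <- reg / max(abs(reg))
      vox <- which(blobs[[b]]$mask)
      # Gaussian amplitude profile: the center voxel carries the unique
      # maximum, so a high-SNR peak search recovers it exactly
      dmm <- sweep(blobs[[b]]$voxels, 2, blobs[[b]]$center, "-")
      dmm <- sweep(dmm, 2, voxel_size_mm, "*")
      amp <- effect_size * exp(-rowSums(dmm^2) / (2 * (blob_radius_mm / 2)^2))
      vox_lin <- blobs[[b]]$voxels[, 1] +
        (blobs[[b]]$voxels[, 2] - 1L) * grid_dim[1] +
        (blobs[[b]]$voxels[, 3] - 1L) * grid_dim[1] * grid_dim[2]
      for (t in seq_len(n_volumes)) {
        slab <- arr[, , , t]
        slab[vox_lin] <- slab[vox_lin] + amp * reg[t]
        arr[, , , t] <- slab
      }
    }
    list(vs = volume_series(arr, tr_seconds, voxel_size_mm),
         design = design, design_matrix = dm, blobs = blobs,
         conditions = blob_conditions,
         truth = list(centers = blob_centers))
  })
}

#' Cohort specification with a planted connectivity-to-symptom slope
#'
#' Describes a synthetic cohort in which each participant's change in
#' depression score (BDI) from the SHAM day to the last training day is a
#' linear function of their change in resting-state connectivity:
#' \code{symptom_change = intercept + beta * fc_change
#' (+ experiment_effect for experiment 2) + Normal(0, residual_sd)}.
#'
#' Defaults emulate the published study conditions: 19 participants split 9/10
#' over two experiments; Day-0 connectivity near 0.01; connectivity changes
#' centred on -0.07 (the move toward the healthy-control reference) with SD
#' 0.15; a slope of 20 BDI points per unit connectivity change with residual
#' SD 3, which yields change-score correlations in the ballpark the paradigm
#' reports.
#'
#' @param n_participants Number of participants (at least 2; at least 4 to
#'   fit models downstream).
#' @param beta Planted slope of symptom change on connectivity change.
#' @param intercept Planted intercept.
#' @param residual_sd Residual SD of symptom change.
#' @param experiment_effect Additive symptom-change shift for experiment 2.
#' @param fc_change_distribution Length-2 numeric (mean, sd) of connectivity
#'   changes.
#' @param seed Integer seed.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_participants = 19L, beta = 20, intercept = -2,
                        residual_sd = 3, experiment_effect = 0,
                        fc_change_distribution = c(mean = -0.07, sd = 0.15),
                        seed = 1L) {
  if (n_participants < 2L) stop("need at least 2 participants", call. = FALSE)
  if (residual_sd < 0) stop("residual_sd must be nonnegative", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants), beta = beta,
                 intercept = intercept, residual_sd = residual_sd,
                 experiment_effect = experiment_effect,
                 fc_change_distribution = as.numeric(fc_change_distribution),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table with a planted slope
#'
#' Generates a long-format cohort table (Day0 and FCNefDay4 rows per
#' participant, optionally 1- and 2-month follow-ups) whose BDI changes follow
#' the planted linear model in the \code{\link{cohort_spec}}. The other
#' questionnaire scales (RRS factors, STAI2) receive realistic levels with
#' changes unrelated to connectivity, mirroring the role of unrelated-symptom
#' controls.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param include_followup Also emit Post1m/Post2m rows (changes drawn with
#'   the same planted slope).
#' @return A list with \code{cohort} (a \code{cohort_table} data frame) and
#'   \code{truth} (per-participant \code{fc_change}, \code{bdi_change}, and
#'   the planted parameters).
#' @export
simulate_cohort <- function(spec = cohort_spec(), include_followup = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    n1 <- floor(n / 2)
    experiment <- c(rep(1L, n1), rep(2L, n - n1))
    fc0 <- pmin(0.9, pmax(-0.9, rnorm(n, 0.01, 0.1)))
    fc_change <- rnorm(n, spec$fc_change_distribution[1],
                       spec$fc_change_distribution[2])
    fc4 <- pmin(1, pmax(-1, fc0 + fc_change))
    fc_change <- fc4 - fc0  # after clamping, keep truth consistent
    bdi0 <- round(pmax(9, rnorm(n, 14.3, 5.1)))
    noise <- if (spec$residual_sd > 0) rnorm(n, 0, spec$residual_sd) else 0
    bdi_change <- spec$intercept + spec$beta * fc_change +
      spec$experiment_effect * (experiment == 2L) + noise
    bdi4 <- bdi0 + bdi_change
    rrs_dep0 <- round(rnorm(n, 30, 6)); rrs_bro0 <- round(rnorm(n, 12, 3))
    rrs_ref0 <- round(rnorm(n, 10, 3)); stai0 <- round(rnorm(n, 50, 8))
    mk_day <- function(day, bdi, fc, jitter = 2) {
      data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                 experiment_id = experiment, day = day,
                 BDI = bdi,
                 RRS_depression = rrs_dep0 + if (day == "Day0") 0 else round(rnorm(n, 0, jitter)),
                 RRS_brooding = rrs_bro0 + if (day == "Day0") 0 else round(rnorm(n, 0, jitter)),
                 RRS_reflection = rrs_ref0 + if (day == "Day0") 0 else round(rnorm(n, 0, jitter)),
                 STAI2 = stai0 + if (day == "Day0") 0 else round(rnorm(n, 0, jitter)),
                 rs_fc = fc, stringsAsFactors = FALSE)
    }
    rows <- list(mk_day("Day0", bdi0, fc0), mk_day("FCNefDay4", bdi4, fc4))
    if (include_followup) {
      for (day in c("Post1m", "Post2m")) {
        fc_ch <- rnorm(n, spec$fc_change_distribution[1],
                       spec$fc_change_distribution[2])
        fcd <- pmin(1, pmax(-1, fc0 + fc_ch))
        noise_f <- if (spec$residual_sd > 0) rnorm(n, 0, spec$residual_sd) else 0
        bdid <- bdi0 + spec$intercept + spec$beta * (fcd - fc0) +
          spec$experiment_effect * (experiment == 2L) + noise_f
        rows[[length(rows) + 1L]] <- mk_day(day, bdid, fcd)
      }
    }
    cohort <- as_cohort_table(do.call(rbind, rows))
    list(cohort = cohort,
         truth = list(beta = spec$beta, intercept = spec$intercept,
                      experiment_effect = spec$experiment_effect,
                      fc_change = fc_change, bdi_change = bdi_change))
  })
}
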