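#' Fisher r-to-z transform and its inverse
#'
#' \code{fisher_z} is the variance-stabilising transform
#' \eqn{z = \mathrm{atanh}(r)} used to average correlation coefficients;
#' \code{inverse_fisher} is \eqn{r = \tanh(z)}.
#'
#' @param r Correlation coefficient(s), strictly inside (-1, 1).
#' @param z Fisher z value(s).
#' @return Transformed numeric vector.
#' @examples
#' fisher_z(0.5)          # 0.5493061
#' inverse_fisher(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) tanh(z)

#' Per-trial functional connectivity
#'
#' The online trial pipeline: the mean signal of each ROI over the session's
#' rest window is subtracted from that ROI's signal, nuisance regressors are
#' projected out, the series is band-pass filtered (online band), and the
#' Pearson correlation of the two ROI signals over the trial's usable
#' induction window is returned.
#'
#' @param roi1,roi2 Full-session ROI mean time series (numeric vectors of
#'   equal length).
#' @param trial_window Length-2 integer (start, end), 1-based inclusive usable
#'   induction window (from \code{\link{segment_session}}).
#' @param rest_window Length-2 integer (start, end) rest window used for
#'   baselining.
#' @param nuisance A \code{nuisance_set}, design matrix, or \code{NULL}.
#' @param config An \code{\link{fcnef_config}}.
#' @return Pearson correlation in [-1, 1].
#' @export
trial_fc <- function(roi1, roi2, trial_window, rest_window, nuisance = NULL,
                     config = fcnef_config()) {
  n <- length(roi1)
  if (length(roi2) != n) stop("ROI series lengths differ", call. = FALSE)
  tw <- as.integer(trial_window); rw <- as.integer(rest_window)
  if (tw[2] - tw[1] + 1L < 3L)
    stop("usable induction window must span at least 3 volumes", call. = FALSE)
  if (tw[1] < 1L || tw[2] > n || rw[1] < 1L || rw[2] > n)
    stop("window outside the session", call. = FALSE)
  rest_idx <- rw[1]:rw[2]
  x <- cbind(roi1 - mean(roi1[rest_idx]),
             roi2 - mean(roi2[rest_idx]))
  x <- regress_out(x, nuisance)
  x <- bandpass(x, config$tr_seconds, config$online_band[1],
                config$online_band[2])
  seg <- x[tw[1]:tw[2], , drop = FALSE]
  if (var(seg[, 1]) == 0 || var(seg[, 2]) == 0)
    stop("degenerate (zero-variance) ROI signal in the induction window",
         call. = FALSE)
  cor(seg[, 1], seg[, 2])
}

#' Baseline connectivity statistics from SHAM trials
#'
#' Fisher-transforms the per-trial correlations from the SHAM day, takes
#' their mean and sample standard deviation in z space, and transforms back:
#' the mean correlation is the participant's baseline and the back-transformed
#' mean +/- 1 SD give the score anchors (score 100 at or below the lower
#' anchor, 50 at the baseline, 0 at or above the upper anchor).
#'
#' The published procedure averages in z space; with
#' \code{anchor_space = "r"} the mean/SD and anchors are computed directly on
#' the correlation scale instead (an alternative reading, kept behind this
#' switch).
#'
#' @param trial_rs Numeric vector of per-trial correlations (all SHAM trials),
#'   each strictly inside (-1, 1); at least two distinct values.
#' @param anchor_space \code{"z"} (default) or \code{"r"}.
#' @return An object of class \code{fcnef_baseline} with fields
#'   \code{mean_z}, \code{sd_z}, \code{mean_r}, \code{lower_anchor_r},
#'   \code{upper_anchor_r}, \code{n_trials_used}, \code{anchor_space}.
#' @export
compute_baseline <- function(trial_rs, anchor_space = c("z", "r")) {
  anchor_space <- match.arg(anchor_space)
  if (length(trial_rs) < 2L)
    stop("need at least two SHAM trials to form a baseline", call. = FALSE)
  z <- fisher_z(trial_rs)
  if (sd(z) == 0)
    stop("SHAM trial correlations have zero variance; baseline is degenerate",
         call. = FALSE)
  if (anchor_space == "z") {
    mean_z <- mean(z); sd_z <- sd(z)
    mean_r <- inverse_fisher(mean_z)
    lower <- inverse_fisher(mean_z - sd_z)
    upper <- inverse_fisher(mean_z + sd_z)
  } else {
    mean_r <- mean(trial_rs); sd_r <- sd(trial_rs)
    mean_z <- fisher_z(mean_r); sd_z <- sd_r  # SD on the r scale
    lower <- mean_r - sd_r
    upper <- mean_r + sd_r
  }
  structure(list(mean_z = mean_z, sd_z = sd_z, mean_r = mean_r,
                 lower_anchor_r = lower, upper_anchor_r = upper,
                 n_trials_used = length(trial_rs),
                 anchor_space = anchor_space),
            class = "fcnef_baseline")
}

#' @export
print.fcnef_baseline <- function(x, ...) {
  cat(sprintf("SHAM-derived baseline FC (%d trials, %s-space anchors)\n",
              x$n_trials_used, x$anchor_space))
  cat(sprintf("  baseline r = %.4f (z = %.4f, SD %.4f)\n",
              x$mean_r, x$mean_z, x$sd_z))
  cat(sprintf("  anchors: score 100 at r <= %.4f, score 0 at r >= %.4f\n",
              x$lower_anchor_r, x$upper_anchor_r))
  invisible(x)
}

#' Map a trial correlation to a 0-100 feedback score
#'
#' Scores are anchored at three printed points: 50 at the baseline
#' correlation, 100 at baseline minus one standard deviation or more
#' negative, 0 at baseline plus one standard deviation or more positive.
#' Between the anchors the score is linear in Fisher-z (or in r when the
#' baseline was built with r-space anchors), and it is clamped to [0, 100]
#' beyond them. More negative connectivity than baseline therefore always
#' earns a higher score.
#'
#' @param r Trial correlation(s) in [-1, 1].
#' @param baseline An \code{fcnef_baseline} from \code{\link{compute_baseline}}.
#' @return Score(s) in [0, 100].
#' @examples
#' b <- compute_baseline(c(0.3, -0.3, 0.1, -0.1))
#' score_trial(b$mean_r, b)           # 50
#' score_trial(b$lower_anchor_r, b)   # 100
#' score_trial(b$upper_anchor_r, b)   # 0
#' @export
score_trial <- function(r, baseline) {
  stopifnot(inherits(baseline, "fcnef_baseline"))
  if (baseline$sd_z <= 0) stop("degenerate baseline", call. = FALSE)
  if (baseline$anchor_space == "z") {
    z <- fisher_z(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    raw <- 50 - 50 * (z - baseline$mean_z) / baseline$sd_z
  } else {
    raw <- 50 - 50 * (r - baseline$mean_r) / baseline$sd_z
  }
  pmin(100, pmax(0, raw))
}

#' SHAM feedback draws
#'
#' The random feedback presented on the SHAM day: raw draws from
#' Normal(mean 50, SD 30.3). The raw draw is retained (so the generating
#' parameters stay recoverable from the record) alongside the value clamped
#' to [0, 100] for display.
#'
#' @param n Number of draws.
#' @param config An \code{\link{fcnef_config}} supplying \code{sham_mean} and
#'   \code{sham_sd}.
#' @return A data frame with columns \code{raw} and \code{display}.
#' @export
sham_score <- function(n = 1, config = fcnef_config()) {
  raw <- rnorm(n, mean = config$sham_mean, sd = config$sham_sd)
  data.frame(raw = raw, display = pmin(100, pmax(0, raw)))
}

#' Score all trials of a neurofeedback session
#'
#' Computes each trial's connectivity with \code{\link{trial_fc}} over the
#' session's segmentation and maps it through \code{\link{score_trial}}
#' against the participant's baseline; in SHAM mode the displayed scores are
#' instead random \code{\link{sham_score}} draws (the computed trial
#' correlations are still recorded).
#'
#' @param session A session bundle from \code{\link{simulate_session}} or a
#'   list with \code{roi1}, \code{roi2}, \code{nuisance}, \code{segments}.
#' @param baseline An \code{fcnef_baseline}; may be \code{NULL} when
#'   \code{sham = TRUE}.
#' @param config An \code{\link{fcnef_config}}.
#' @param sham Replace computed scores with random SHAM feedback.
#' @return An object of class \code{fcnef_session_scores}: a data frame with
#'   columns \code{trial, r, z, score, sham} and attribute
#'   \code{mean_score}.
#' @export
run_fcnef_session <- function(session, baseline = NULL,
                              config = fcnef_config(), sham = FALSE) {
  seg <- session$segments
  stopifnot(inherits(seg, "segment_index"))
  if (!sham && is.null(baseline))
    stop("a baseline is required unless sham = TRUE", call. = FALSE)
  n_trials <- nrow(seg$trials)
  rs <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    rs[i] <- trial_fc(session$roi1, session$roi2,
                      trial_window = c(seg$trials$induction_used_start[i],
                                       seg$trials$induction_used_end[i]),
                      rest_window = seg$rest_used,
                      nuisance = session$nuisance,
                      config = config)
  }
  if (sham) {
    draws <- sham_score(n_trials, config)
    score <- draws$display
  } else {
    score <- score_trial(rs, baseline)
  }
  out <- data.frame(trial = seq_len(n_trials), r = rs, z = atanh(rs),
                    score = score, sham = sham)
  attr(out, "mean_score") <- mean(score)
  class(out) <- c("fcnef_session_scores", class(out))
  out
}

#' @export
print.fcnef_session_scores <- function(x, ...) {
  cat(sprintf("FCNef session scores (%s feedback), mean score %.2f\n",
              if (x$sham[1]) "SHAM" else "real", attr(x, "mean_score")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
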