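#' Offline resting-state functional connectivity
#'
#' The full offline pipeline for one resting run: nuisance regression (motion,
#' global/CSF/grey-matter means and all their derivatives), censoring of
#' frames with framewise displacement above threshold, zero-phase Butterworth
#' band-pass in the resting band (0.008--0.1 Hz by default), and the Pearson
#' correlation between the two ROI series.
#'
#' @param roi1,roi2 ROI mean time series (numeric vectors of equal length).
#' @param motion n x 6 motion-parameter matrix.
#' @param tissue_means n x 3 matrix with columns \code{global, csf, gm}.
#' @param config An \code{\link{fcnef_config}}.
#' @return Pearson correlation in [-1, 1].
#' @export
resting_fc <- function(roi1, roi2, motion, tissue_means,
                       config = fcnef_config()) {
  n <- length(roi1)
  if (length(roi2) != n || nrow(as.matrix(motion)) != n)
    stop("roi series and motion must have equal length", call. = FALSE)
  nuis <- build_nuisance(motion, tissue_means, include_derivatives = TRUE)
  x <- regress_out(cbind(roi1, roi2), nuis)
  fd <- compute_fd(as.matrix(motion), config$sphere_head_radius_mm)
  sc <- scrub(x, fd, config$fd_threshold_mm)
  if (length(sc$kept) < 3L)
    stop("fewer than 3 volumes survive scrubbing", call. = FALSE)
  x <- bandpass(sc$series, config$tr_seconds, config$resting_band[1],
                config$resting_band[2])
  cor(x[, 1], x[, 2])
}

#' Change scores from a cohort table
#'
#' Subtracts each participant's Day-0 questionnaire scores and resting-state
#' connectivity from their values at a later horizon (last training day or a
#' follow-up). Participants missing either row are dropped with a warning.
#'
#' @param cohort A \code{cohort_table} (see \code{\link{read_cohort_table}}).
#' @param horizon \code{"FCNefDay4"} (default), \code{"Post1m"} or
#'   \code{"Post2m"}.
#' @return A data frame of class \code{change_scores} with one row per
#'   participant: \code{participant_id, experiment_id, horizon, delta_rs_fc,
#'   delta_BDI, delta_RRS_depression, delta_RRS_brooding,
#'   delta_RRS_reflection, delta_STAI2}.
#' @export
change_scores <- function(cohort, horizon = "FCNefDay4") {
  cohort <- as_cohort_table(as.data.frame(cohort))
  if (!horizon %in% setdiff(DAY_LEVELS, "Day0"))
    stop("horizon must be one of ",
         paste(setdiff(DAY_LEVELS, "Day0"), collapse = ", "), call. = FALSE)
  d0 <- cohort[cohort$day == "Day0", ]
  dh <- cohort[cohort$day == horizon, ]
  common <- intersect(d0$participant_id, dh$participant_id)
  missing_ids <- setdiff(union(d0$participant_id, dh$participant_id), common)
  if (length(missing_ids))
    warning("dropping participant(s) missing Day0 or ", horizon, " rows: ",
            paste(missing_ids, collapse = ", "))
  if (!length(common)) stop("no participant has both rows", call. = FALSE)
  d0 <- d0[match(common, d0$participant_id), ]
  dh <- dh[match(common, dh$participant_id), ]
  out <- data.frame(participant_id = common,
                    experiment_id = d0$experiment_id,
                    horizon = horizon,
                    delta_rs_fc = dh$rs_fc - d0$rs_fc,
                    delta_BDI = dh$BDI - d0$BDI,
                    delta_RRS_depression = dh$RRS_depression - d0$RRS_depression,
                    delta_RRS_brooding = dh$RRS_brooding - d0$RRS_brooding,
                    delta_RRS_reflection = dh$RRS_reflection - d0$RRS_reflection,
                    delta_STAI2 = dh$STAI2 - d0$STAI2,
                    stringsAsFactors = FALSE)
  class(out) <- c("change_scores", class(out))
  out
}

#' Outlier inclusion mask by the k-SD rule
#'
#' Flags values more than \code{k} standard deviations above or below the
#' mean for exclusion. The mean and SD are computed once over all values
#' (single pass, candidate included); if the values have zero variance,
#' everything is included.
#'
#' @param values Numeric vector (at least 3 values).
#' @param k Number of SDs (default 2).
#' @return Logical vector, \code{TRUE} = include.
#' @export
exclude_outliers <- function(values, k = 2) .ksd_include(values, k)

.ksd_include <- function(values, k) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}

#' Linear change-score model (symptom change on connectivity change)
#'
#' Fits the group-level model relating a questionnaire change score to the
#' change in targeted resting-state connectivity, optionally with an
#' experiment main effect and its interaction with the connectivity change.
#' With one change score per participant there is no replicated grouping, so
#' the mixed-effects formulation reduces to an ordinary linear model fit by
#' maximum likelihood; a random intercept would only be identified for
#' repeated-measures inputs (see
#' \code{\link{repeated_measures_task_model}}).
#'
#' Outlier exclusion (the k-SD rule on the outcome change scores) is applied
#' before fitting when \code{exclude_outliers = TRUE}.
#'
#' @param cs A \code{change_scores} data frame.
#' @param outcome One of \code{"BDI"}, \code{"RRS_depression"},
#'   \code{"RRS_brooding"}, \code{"RRS_reflection"}, \code{"STAI2"}.
#' @param include_experiment_interaction Add experiment main effect and
#'   its interaction with connectivity change.
#' @param exclude_outliers Apply the k-SD exclusion rule to the outcome.
#' @param k_sd The k of the exclusion rule.
#' @return An object of class \code{fcnef_change_fit} wrapping the
#'   \code{\link[stats]{lm}} fit, with \code{coefficients}, \code{anova}
#'   (F table), \code{logLik}, \code{AIC}, \code{formula}, \code{n_used},
#'   \code{outcome}, and the fitted data.
#' @export
fit_change_model <- function(cs, outcome = "BDI",
                             include_experiment_interaction = FALSE,
                             exclude_outliers = TRUE, k_sd = 2) {
  ycol <- paste0("delta_", outcome)
  if (!ycol %in% names(cs)) stop("unknown outcome: ", outcome, call. = FALSE)
  df <- data.frame(delta_outcome = cs[[ycol]],
                   delta_rs_fc = cs$delta_rs_fc,
                   experiment = factor(cs$experiment_id),
                   participant_id = cs$participant_id,
                   stringsAsFactors = FALSE)
  if (exclude_outliers) {
    keep <- .ksd_include(df$delta_outcome, k = k_sd)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) < 4L)
    stop("need at least 4 records to fit the change model", call. = FALSE)
  form <- if (include_experiment_interaction)
    delta_outcome ~ delta_rs_fc * experiment else delta_outcome ~ delta_rs_fc
  if (include_experiment_interaction && length(unique(df$experiment)) < 2L)
    stop("experiment term requested but only one experiment present",
         call. = FALSE)
  fit <- lm(form, data = df)
  if (any(!is.finite(coef(fit))))
    stop("collinear design: coefficients not estimable", call. = FALSE)
  structure(list(fit = fit,
                 coefficients = coef(summary(fit)),
                 anova = stats::anova(fit),
                 logLik = as.numeric(logLik(fit)),
                 AIC = stats::AIC(fit),
                 formula = deparse(form),
                 n_used = nrow(df),
                 outcome = outcome,
                 data = df),
            class = "fcnef_change_fit")
}

#' @export
print.fcnef_change_fit <- function(x, ...) {
  cat(sprintf("Change-score model: %s (n = %d)\n", x$formula, x$n_used))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("logLik %.3f, AIC %.2f\n", x$logLik, x$AIC))
  invisible(x)
}

#' @export
summary.fcnef_change_fit <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("Outcome: change in %s; n = %d\n", object$outcome,
              object$n_used))
  print(s)
  cat("ANOVA:\n"); print(object$anova)
  invisible(s)
}

#' @export
coef.fcnef_change_fit <- function(object, ...) coef(object$fit)

#' @export
predict.fcnef_change_fit <- function(object, newdata = NULL, ...) {
  predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.fcnef_change_fit <- function(object, ...) residuals(object$fit)

#' @export
logLik.fcnef_change_fit <- function(object, ...) logLik(object$fit)

#' @export
plot.fcnef_change_fit <- function(x, ...) {
  graphics::plot(x$data$delta_rs_fc, x$data$delta_outcome,
                 xlab = "change in rs-FC",
                 ylab = paste("change in", x$outcome), ...)
  graphics::abline(lm(delta_outcome ~ delta_rs_fc, data = x$data))
  invisible(x)
}

#' Likelihood-ratio test between nested change-score models
#'
#' Compares two models fit to the same data by maximum likelihood:
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} on degrees of freedom equal
#' to the difference in parameter counts, with an upper-tail chi-square
#' p-value.
#'
#' @param fit_full,fit_reduced \code{fcnef_change_fit} objects (or any objects
#'   with \code{logLik} methods); the reduced model must be nested in the
#'   full one and fit to the same observations.
#' @return A list with \code{chi2}, \code{df}, \code{p},
#'   \code{aic_full}, \code{aic_reduced}.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  ll_f <- logLik(if (inherits(fit_full, "fcnef_change_fit")) fit_full$fit else fit_full)
  ll_r <- logLik(if (inherits(fit_reduced, "fcnef_change_fit")) fit_reduced$fit else fit_reduced)
  if (attr(ll_f, "nobs") != attr(ll_r, "nobs"))
    stop("models were fit to different numbers of observations", call. = FALSE)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0)
    stop("the full model has fewer parameters than the reduced model",
         call. = FALSE)
  chi2 <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p,
       aic_full = -2 * as.numeric(ll_f) + 2 * attr(ll_f, "df"),
       aic_reduced = -2 * as.numeric(ll_r) + 2 * attr(ll_r, "df"))
}

#' Leave-one-out prediction of symptom change
#'
#' Refits the change-score model with each participant left out in turn,
#' predicts the held-out participant's symptom change from their connectivity
#' change, and reports the Pearson correlation between actual and predicted
#' changes (the overfitting check for the group model).
#'
#' @param cs A \code{change_scores} data frame (at least 5 records).
#' @param outcome Outcome scale, as in \code{\link{fit_change_model}}.
#' @param exclude_outliers,k_sd Outlier rule applied once to the full set
#'   before the leave-one-out loop.
#' @return A list of class \code{fcnef_loo}: \code{predicted}, \code{actual},
#'   \code{participant_id}, \code{r}, \code{p}.
#' @export
loo_predict <- function(cs, outcome = "BDI", exclude_outliers = TRUE,
                        k_sd = 2) {
  ycol <- paste0("delta_", outcome)
  if (!ycol %in% names(cs)) stop("unknown outcome: ", outcome, call. = FALSE)
  df <- data.frame(delta_outcome = cs[[ycol]], delta_rs_fc = cs$delta_rs_fc,
                   participant_id = cs$participant_id,
                   stringsAsFactors = FALSE)
  if (exclude_outliers) {
    df <- df[.ksd_include(df$delta_outcome, k = k_sd), ,
             drop = FALSE]
  }
  n <- nrow(df)
  if (n < 5L) stop("need at least 5 records for leave-one-out", call. = FALSE)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- lm(delta_outcome ~ delta_rs_fc, data = df[-i, ])
    pred[i] <- predict(fit_i, newdata = df[i, , drop = FALSE])
  }
  ct <- stats::cor.test(df$delta_outcome, pred)
  structure(list(predicted = pred, actual = df$delta_outcome,
                 participant_id = df$participant_id,
                 r = unname(ct$estimate), p = ct$p.value),
            class = "fcnef_loo")
}

#' @export
print.fcnef_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out prediction: r(actual, predicted) = %.3f (p = %.3g, n = %d)\n",
              x$r, x$p, length(x$actual)))
  invisible(x)
}

#' @export
plot.fcnef_loo <- function(x, ...) {
  graphics::plot(x$actual, x$predicted, xlab = "actual change",
                 ylab = "predicted change (leave-one-out)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Correlation between connectivity change and symptom change
#'
#' Pearson correlation with a two-sided t-based p-value, with the k-SD
#' outlier rule optionally applied to the outcome first.
#'
#' @param cs A \code{change_scores} data frame (at least 3 records).
#' @param outcome Outcome scale, as in \code{\link{fit_change_model}}.
#' @param exclude_outliers,k_sd Outlier rule on the outcome change scores.
#' @return A list with \code{r}, \code{p}, \code{n}.
#' @export
correlate_changes <- function(cs, outcome = "BDI", exclude_outliers = TRUE,
                              k_sd = 2) {
  ycol <- paste0("delta_", outcome)
  if (!ycol %in% names(cs)) stop("unknown outcome: ", outcome, call. = FALSE)
  y <- cs[[ycol]]; x <- cs$delta_rs_fc
  if (exclude_outliers && length(y) >= 3L) {
    keep <- .ksd_include(y, k = k_sd)
    y <- y[keep]; x <- x[keep]
  }
  if (length(y) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(y) == 0 || sd(x) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y))
}

#' Mixed model of task scores over training days
#'
#' Fits the repeated-measures model of session feedback scores: a fixed
#' linear effect of training day and a random intercept per participant
#' (maximum likelihood), and reports the main-effect ANOVA for day
#' (Satterthwaite degrees of freedom).
#'
#' @param task_scores Data frame with columns \code{participant_id},
#'   \code{day} (numeric training day, e.g. 1--4), \code{score}.
#' @return A list of class \code{fcnef_task_fit}: the \code{lme4} fit,
#'   fixed-effect \code{coefficients}, \code{anova} table, \code{logLik},
#'   \code{AIC}, variance components \code{varcomp}.
#' @export
repeated_measures_task_model <- function(task_scores) {
  req <- c("participant_id", "day", "score")
  if (!all(req %in% names(task_scores)))
    stop("task_scores needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  days_per <- tapply(task_scores$day, task_scores$participant_id,
                     function(d) length(unique(d)))
  if (max(days_per) < 2L)
    stop("need at least two days per participant", call. = FALSE)
  fit <- lmerTest::lmer(score ~ day + (1 | participant_id),
                        data = task_scores, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit,
                 coefficients = coef(summary(fit)),
                 anova = stats::anova(fit),
                 logLik = as.numeric(logLik(fit)),
                 AIC = stats::AIC(fit),
                 varcomp = stats::setNames(vc$sdcor, vc$grp)),
            class = "fcnef_task_fit")
}

#' @export
print.fcnef_task_fit <- function(x, ...) {
  cat("Task-score mixed model: score ~ day + (1 | participant)\n")
  stats::printCoefmat(x$coefficients)
  cat("Random-effect SDs:\n"); print(x$varcomp)
  invisible(x)
}

#' @export
coef.fcnef_task_fit <- function(object, ...) lme4::fixef(object$fit)
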