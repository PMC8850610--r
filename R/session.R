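#' Trial schedule for a neurofeedback session
#'
#' Encodes the fixed timing of one feedback session: an initial rest period,
#' then a sequence of trials each consisting of an "equals" fixation period, a
#' "plus" period whose first part is the induction period (during which the
#' participant tries to modulate connectivity) and whose final seconds are the
#' online calculation window, followed by the feedback display.
#'
#' Defaults encode the published paradigm: 150 s rest with the first 10
#' volumes discarded, six trials of 14 s equals + 42 s plus, of which the
#' first 40 s are the induction period; the first 2 s of each induction are
#' discarded for the hemodynamic delay so 38 s enter the connectivity
#' computation, and the last 2 s of the plus period are the calculation
#' window. The feedback display duration is not a published constant; the
#' default (26/6 s) is the package's inference that makes a default six-trial
#' session span 512 volumes at TR 1 s, matching the published session length.
#'
#' @param rest_seconds Initial rest duration (s).
#' @param rest_discard_volumes Leading rest volumes excluded from the rest
#'   window used for baselining.
#' @param n_trials Number of trials.
#' @param equals_seconds Duration of the pre-trial fixation (s).
#' @param plus_seconds Duration of the plus period (s); must equal
#'   \code{induction_seconds + calculation_seconds}.
#' @param induction_seconds Induction period duration (s).
#' @param hemodynamic_discard_seconds Seconds discarded from the start of each
#'   induction period; must be less than \code{induction_seconds}.
#' @param calculation_seconds Online FC calculation window (s).
#' @param feedback_seconds Feedback display duration (s).
#' @return An object of class \code{trial_schedule}.
#' @examples
#' sched <- trial_schedule()
#' segment_session(sched, tr_seconds = 1, n_volumes = 512)
#' @export
trial_schedule <- function(rest_seconds = 150,
                           rest_discard_volumes = 10L,
                           n_trials = 6L,
                           equals_seconds = 14,
                           plus_seconds = 42,
                           induction_seconds = 40,
                           hemodynamic_discard_seconds = 2,
                           calculation_seconds = 2,
                           feedback_seconds = 26 / 6) {
  sched <- list(rest_seconds = rest_seconds,
                rest_discard_volumes = as.integer(rest_discard_volumes),
                n_trials = as.integer(n_trials),
                equals_seconds = equals_seconds,
                plus_seconds = plus_seconds,
                induction_seconds = induction_seconds,
                hemodynamic_discard_seconds = hemodynamic_discard_seconds,
                calculation_seconds = calculation_seconds,
                feedback_seconds = feedback_seconds)
  if (sched$n_trials < 1L) stop("need at least one trial", call. = FALSE)
  if (sched$rest_seconds < 0 || sched$rest_discard_volumes < 0L)
    stop("rest parameters must be nonnegative", call. = FALSE)
  if (sched$induction_seconds + sched$calculation_seconds != sched$plus_seconds)
    stop("induction_seconds + calculation_seconds must equal plus_seconds (",
         sched$induction_seconds, " + ", sched$calculation_seconds,
         " != ", sched$plus_seconds, ")", call. = FALSE)
  if (sched$hemodynamic_discard_seconds >= sched$induction_seconds)
    stop("hemodynamic discard must be shorter than the induction period",
         call. = FALSE)
  if (sched$feedback_seconds < 0)
    stop("feedback_seconds must be nonnegative", call. = FALSE)
  class(sched) <- "trial_schedule"
  sched
}

#' Total session duration implied by a schedule
#'
#' @param schedule A \code{\link{trial_schedule}}.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  schedule$rest_seconds + schedule$n_trials *
    (schedule$equals_seconds + schedule$plus_seconds + schedule$feedback_seconds)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: %g s rest (first %d volumes discarded) + %d trials\n",
              x$rest_seconds, x$rest_discard_volumes, x$n_trials))
  cat(sprintf("  per trial: %g s equals, %g s plus (%g s induction incl. %g s discard, %g s calculation), %g s feedback\n",
              x$equals_seconds, x$plus_seconds, x$induction_seconds,
              x$hemodynamic_discard_seconds, x$calculation_seconds,
              x$feedback_seconds))
  cat(sprintf("  total %.1f s\n", schedule_duration(x)))
  invisible(x)
}

# seconds [a, b) -> 1-based inclusive volume window; partial volumes floored
window_volumes <- function(start_s, dur_s, tr) {
  start0 <- floor(start_s / tr)        # 0-based first volume
  len <- floor(dur_s / tr)
  c(start = start0 + 1, end = start0 + len)
}

#' Map a trial schedule to volume-index windows
#'
#' Discretises a \code{\link{trial_schedule}} at a given TR into per-trial
#' volume windows. Windows are 1-based inclusive \code{(start, end)} pairs;
#' durations that are not whole multiples of the TR are floored so partial
#' volumes are never included. \code{rest_used} excludes the discarded leading
#' rest volumes; \code{induction_used} excludes the hemodynamic discard at the
#' start of each induction period.
#'
#' @param schedule A \code{\link{trial_schedule}}.
#' @param tr_seconds Repetition time (s).
#' @param n_volumes Number of volumes in the session; must cover the schedule.
#' @return An object of class \code{segment_index}: a list with \code{rest_used}
#'   (one window) and a data frame \code{trials} with columns
#'   \code{trial, equals_start, equals_end, induction_used_start,
#'   induction_used_end, calculation_start, calculation_end, feedback_start,
#'   feedback_end}, plus \code{labels}, a per-volume factor in
#'   \code{rest, equals, induction, calculation, feedback, discard}.
#' @export
segment_session <- function(schedule, tr_seconds, n_volumes) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  needed <- floor(schedule_duration(schedule) / tr_seconds)
  if (n_volumes < needed)
    stop("session too short: schedule needs ", needed, " volumes at TR ",
         tr_seconds, " s but only ", n_volumes, " available", call. = FALSE)

  rest_win <- window_volumes(0, schedule$rest_seconds, tr_seconds)
  rest_used <- c(start = unname(rest_win["start"]) + schedule$rest_discard_volumes,
                 end = unname(rest_win["end"]))
  if (rest_used["start"] > rest_used["end"])
    stop("rest discard leaves no rest volumes", call. = FALSE)

  trial_len <- schedule$equals_seconds + schedule$plus_seconds +
    schedule$feedback_seconds
  rows <- vector("list", schedule$n_trials)
  for (i in seq_len(schedule$n_trials)) {
    t0 <- schedule$rest_seconds + (i - 1) * trial_len
    eq <- window_volumes(t0, schedule$equals_seconds, tr_seconds)
    ind_start_s <- t0 + schedule$equals_seconds
    ind_used <- window_volumes(ind_start_s + schedule$hemodynamic_discard_seconds,
                               schedule$induction_seconds -
                                 schedule$hemodynamic_discard_seconds,
                               tr_seconds)
    calc <- window_volumes(ind_start_s + schedule$induction_seconds,
                           schedule$calculation_seconds, tr_seconds)
    fb <- window_volumes(ind_start_s + schedule$plus_seconds,
                         schedule$feedback_seconds, tr_seconds)
    rows[[i]] <- data.frame(trial = i,
                            equals_start = eq["start"], equals_end = eq["end"],
                            induction_used_start = ind_used["start"],
                            induction_used_end = ind_used["end"],
                            calculation_start = calc["start"],
                            calculation_end = calc["end"],
                            feedback_start = fb["start"],
                            feedback_end = fb["end"],
                            row.names = NULL)
  }
  trials <- do.call(rbind, rows)

  labels <- factor(rep("discard", n_volumes),
                   levels = c("rest", "equals", "induction", "calculation",
                              "feedback", "discard"))
  mark <- function(lab, s, e) {
    idx <- seq.int(s, e)
    idx <- idx[idx >= 1 & idx <= n_volumes]
    labels[idx] <<- lab
  }
  mark("rest", rest_used["start"], rest_used["end"])
  for (i in seq_len(nrow(trials))) {
    mark("equals", trials$equals_start[i], trials$equals_end[i])
    mark("induction", trials$induction_used_start[i], trials$induction_used_end[i])
    mark("calculation", trials$calculation_start[i], trials$calculation_end[i])
    if (trials$feedback_end[i] >= trials$feedback_start[i])
      mark("feedback", trials$feedback_start[i], trials$feedback_end[i])
  }

  structure(list(rest_used = rest_used, trials = trials, labels = labels,
                 tr_seconds = tr_seconds, n_volumes = n_volumes),
            class = "segment_index")
}

#' @export
print.segment_index <- function(x, ...) {
  cat(sprintf("Session segmentation (%d volumes at TR %g s)\n",
              x$n_volumes, x$tr_seconds))
  cat(sprintf("  rest used: volumes %d-%d\n", x$rest_used["start"],
              x$rest_used["end"]))
  print(x$trials, row.names = FALSE)
  invisible(x)
}

#' Read or write a trial schedule as YAML
#'
#' @param path File path.
#' @param schedule A \code{\link{trial_schedule}}.
#' @return \code{read_schedule} returns a \code{trial_schedule};
#'   \code{write_schedule} returns \code{path} invisibly.
#' @export
read_schedule <- function(path) {
  do.call(trial_schedule, yaml::read_yaml(path))
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  yaml::write_yaml(unclass(schedule), path)
  invisible(path)
}
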