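#' Pipeline configuration
#'
#' All numeric constants used by the online and offline connectivity pipelines
#' live in one validated object: the repetition time, the two Butterworth pass
#' bands, the framewise-displacement censoring threshold, ROI geometry, the
#' volume-discard rules, the outlier rule, and the parameters of the SHAM
#' feedback distribution.
#'
#' Defaults follow the published paradigm: TR 1 s; online pass band
#' 0.008--0.3 Hz (trial-wise feedback); resting-state pass band 0.008--0.1 Hz;
#' FD threshold 0.5 mm with a 50 mm head radius for the rotation terms; 8 mm
#' sphere ROIs; the first 10 volumes of every session discarded for
#' steady-state magnetisation; 2 s of each induction period discarded for the
#' hemodynamic delay; outliers beyond 2 SD excluded; SHAM feedback drawn from
#' Normal(50, 30.3).
#'
#' @param tr_seconds Repetition time in seconds.
#' @param online_band Length-2 numeric, low/high pass-band edges in Hz for the
#'   online (trial feedback) pipeline.
#' @param resting_band Length-2 numeric, pass-band edges in Hz for the offline
#'   resting-state pipeline.
#' @param fd_threshold_mm Framewise-displacement threshold in mm; frames above
#'   it are spike-regressed (online) or removed (offline).
#' @param roi_radius_mm Radius of the spherical ROIs in mm.
#' @param sphere_head_radius_mm Head radius in mm used to convert rotational
#'   displacement to arc length in the FD formula.
#' @param steady_state_discard_volumes Leading volumes dropped from every
#'   session.
#' @param hemodynamic_discard_seconds Seconds dropped from the start of each
#'   induction period.
#' @param outlier_k_sd Number of standard deviations beyond which change
#'   scores are excluded from group analyses.
#' @param sham_mean,sham_sd Mean and SD of the Normal distribution that SHAM
#'   feedback scores are drawn from.
#' @param rng_seed Integer seed recorded with the configuration.
#'
#' @return An object of class \code{fcnef_config} (a validated named list).
#' @examples
#' cfg <- fcnef_config()
#' cfg$online_band
#' @export
fcnef_config <- function(tr_seconds = 1.0,
                         online_band = c(0.008, 0.3),
                         resting_band = c(0.008, 0.1),
                         fd_threshold_mm = 0.5,
                         roi_radius_mm = 8,
                         sphere_head_radius_mm = 50,
                         steady_state_discard_volumes = 10L,
                         hemodynamic_discard_seconds = 2,
                         outlier_k_sd = 2,
                         sham_mean = 50,
                         sham_sd = 30.3,
                         rng_seed = 1L) {
  cfg <- list(
    tr_seconds = tr_seconds,
    online_band = as.numeric(online_band),
    resting_band = as.numeric(resting_band),
    fd_threshold_mm = fd_threshold_mm,
    roi_radius_mm = roi_radius_mm,
    sphere_head_radius_mm = sphere_head_radius_mm,
    steady_state_discard_volumes = as.integer(steady_state_discard_volumes),
    hemodynamic_discard_seconds = hemodynamic_discard_seconds,
    outlier_k_sd = outlier_k_sd,
    sham_mean = sham_mean,
    sham_sd = sham_sd,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "fcnef_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "fcnef_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$tr_seconds) || cfg$tr_seconds <= 0)
    stop("tr_seconds must be a positive number", call. = FALSE)
  nyquist <- 1 / (2 * cfg$tr_seconds)
  for (band_name in c("online_band", "resting_band")) {
    band <- cfg[[band_name]]
    if (length(band) != 2L || !all(is.finite(band)))
      stop(band_name, " must be two finite numbers", call. = FALSE)
    if (band[1] <= 0 || band[1] >= band[2])
      stop(band_name, ": need 0 < low < high", call. = FALSE)
    if (band[2] >= nyquist)
      stop(band_name, ": high edge must be below the Nyquist frequency ",
           signif(nyquist, 4), " Hz", call. = FALSE)
  }
  if (!num1(cfg$fd_threshold_mm) || cfg$fd_threshold_mm <= 0)
    stop("fd_threshold_mm must be positive", call. = FALSE)
  if (!num1(cfg$roi_radius_mm) || cfg$roi_radius_mm <= 0)
    stop("roi_radius_mm must be positive", call. = FALSE)
  if (!num1(cfg$sphere_head_radius_mm) || cfg$sphere_head_radius_mm <= 0)
    stop("sphere_head_radius_mm must be positive", call. = FALSE)
  if (cfg$steady_state_discard_volumes < 0L)
    stop("steady_state_discard_volumes must be nonnegative", call. = FALSE)
  if (!num1(cfg$hemodynamic_discard_seconds) || cfg$hemodynamic_discard_seconds < 0)
    stop("hemodynamic_discard_seconds must be nonnegative", call. = FALSE)
  if (!num1(cfg$outlier_k_sd) || cfg$outlier_k_sd <= 0)
    stop("outlier_k_sd must be positive", call. = FALSE)
  if (!num1(cfg$sham_sd) || cfg$sham_sd <= 0)
    stop("sham_sd must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.fcnef_config <- function(x, ...) {
  cat("FCNef pipeline configuration\n")
  cat(sprintf("  TR: %g s (Nyquist %g Hz)\n", x$tr_seconds, 1 / (2 * x$tr_seconds)))
  cat(sprintf("  online band:  %g-%g Hz\n", x$online_band[1], x$online_band[2]))
  cat(sprintf("  resting band: %g-%g Hz\n", x$resting_band[1], x$resting_band[2]))
  cat(sprintf("  FD threshold: %g mm (head radius %g mm)\n",
              x$fd_threshold_mm, x$sphere_head_radius_mm))
  cat(sprintf("  ROI radius: %g mm\n", x$roi_radius_mm))
  cat(sprintf("  discards: %d leading volumes, %g s hemodynamic\n",
              x$steady_state_discard_volumes, x$hemodynamic_discard_seconds))
  cat(sprintf("  outlier rule: %g SD\n", x$outlier_k_sd))
  cat(sprintf("  SHAM feedback: Normal(%g, %g)\n", x$sham_mean, x$sham_sd))
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param cfg An \code{fcnef_config} object.
#' @return \code{read_config} returns an \code{fcnef_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(fcnef_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(fcnef_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
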