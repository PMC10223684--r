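#' Classifier configuration
#'
#' All thresholds and filter parameters of the bout-classification algorithm,
#' externally configurable. Angle thresholds are in degrees on tilt angles in
#' `[0, 180]`; the defaults are the published values of the algorithm.
#'
#' The profiling thresholds (`vt_upright_profile_deg` etc.) decide whether the
#' whole recording belongs to an "upright-likely" candidate, which selects the
#' movement-intensity (summed windowed SD) branch of upright detection; the
#' window thresholds (`vt_upright_window_deg`, `ap_upright_window_deg`) are
#' applied per 0.1 s window. Sitting/lying labelling of candidate bouts uses
#' the fixed anterior-posterior thresholds `ap_lying_fixed_deg` /
#' `ap_sitting_fixed_deg`; non-upright segments are labelled adaptively
#' relative to the preceding upright bout via `lying_ratio`.
#'
#' @param vt_upright_profile_deg,ml_upright_profile_deg,ap_upright_profile_deg
#'   Whole-recording profiling thresholds on the mean filtered vertical,
#'   mediolateral and anterior-posterior tilt angles (degrees; defaults 150,
#'   90, 90). The ceiling of each mean is compared with `>=`.
#' @param vt_upright_window_deg,ap_upright_window_deg Per-window tilt
#'   thresholds for upright detection (degrees; defaults 140, 75).
#' @param ap_lying_fixed_deg,ap_sitting_fixed_deg Fixed anterior-posterior
#'   thresholds for relabelling candidate upright bouts (degrees; defaults 40,
#'   80; lying must be below sitting).
#' @param lying_ratio Adaptive divisor: a non-upright segment is lying when
#'   its mean anterior-posterior tilt is below the preceding upright bout's
#'   mean divided by this ratio (default 2.5).
#' @param mode `"gated"` (default) additionally requires the per-window tilt
#'   test in the upright-likely branch; `"strict"` follows the
#'   movement-intensity test alone.
#' @param min_bout_s Minimum bout duration (s); shorter bouts are absorbed
#'   into their longer neighbour. Default 0 (no minimum).
#' @param accel_cutoff_hz Low-pass cutoff for the acceleration axes (Hz,
#'   default 17).
#' @param std_cutoff_hz Low-pass cutoff for the summed windowed SD series
#'   (Hz, default 1), applied at the window rate.
#' @param tilt_cutoff_hz Low-pass cutoff for the tilt-angle series (Hz,
#'   default 0.25), applied at the window rate.
#' @param window_s Window length in seconds (default 0.1, i.e. 10 samples at
#'   100 Hz).
#' @param target_rate_hz Uniform resampling rate (Hz, default 100).
#' @param filter_order Butterworth order for all filters (default 2; applied
#'   forward-backward, so the effective response is the squared magnitude).
#' @return An object of class `algo_config` (named list).
#' @export
algo_config <- function(vt_upright_profile_deg = 150,
                        ml_upright_profile_deg = 90,
                        ap_upright_profile_deg = 90,
                        vt_upright_window_deg = 140,
                        ap_upright_window_deg = 75,
                        ap_lying_fixed_deg = 40,
                        ap_sitting_fixed_deg = 80,
                        lying_ratio = 2.5,
                        mode = c("gated", "strict"),
                        min_bout_s = 0,
                        accel_cutoff_hz = 17,
                        std_cutoff_hz = 1,
                        tilt_cutoff_hz = 0.25,
                        window_s = 0.1,
                        target_rate_hz = 100,
                        filter_order = 2) {
  mode <- match.arg(mode)
  cfg <- list(
    vt_upright_profile_deg = vt_upright_profile_deg,
    ml_upright_profile_deg = ml_upright_profile_deg,
    ap_upright_profile_deg = ap_upright_profile_deg,
    vt_upright_window_deg = vt_upright_window_deg,
    ap_upright_window_deg = ap_upright_window_deg,
    ap_lying_fixed_deg = ap_lying_fixed_deg,
    ap_sitting_fixed_deg = ap_sitting_fixed_deg,
    lying_ratio = lying_ratio,
    mode = mode,
    min_bout_s = min_bout_s,
    accel_cutoff_hz = accel_cutoff_hz,
    std_cutoff_hz = std_cutoff_hz,
    tilt_cutoff_hz = tilt_cutoff_hz,
    window_s = window_s,
    target_rate_hz = target_rate_hz,
    filter_order = filter_order
  )
  validate_algo_config(cfg)
  structure(cfg, class = "algo_config")
}

validate_algo_config <- function(cfg) {
  ang <- c("vt_upright_profile_deg", "ml_upright_profile_deg",
           "ap_upright_profile_deg", "vt_upright_window_deg",
           "ap_upright_window_deg", "ap_lying_fixed_deg",
           "ap_sitting_fixed_deg")
  for (k in ang) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 180)
      stop(k, " must lie in (0, 180) degrees", call. = FALSE)
  }
  if (cfg$lying_ratio <= 1)
    stop("lying_ratio must exceed 1", call. = FALSE)
  if (cfg$ap_lying_fixed_deg >= cfg$ap_sitting_fixed_deg)
    stop("ap_lying_fixed_deg must be below ap_sitting_fixed_deg", call. = FALSE)
  if (!cfg$mode %in% c("gated", "strict"))
    stop("mode must be 'gated' or 'strict'", call. = FALSE)
  for (k in c("accel_cutoff_hz", "std_cutoff_hz", "tilt_cutoff_hz",
              "window_s", "target_rate_hz"))
    if (cfg[[k]] <= 0) stop(k, " must be positive", call. = FALSE)
  if (cfg$min_bout_s < 0) stop("min_bout_s must be >= 0", call. = FALSE)
  if (cfg$filter_order < 1 || cfg$filter_order != round(cfg$filter_order))
    stop("filter_order must be a positive integer", call. = FALSE)
  if (cfg$accel_cutoff_hz >= cfg$target_rate_hz / 2)
    stop("accel_cutoff_hz must be below the Nyquist frequency", call. = FALSE)
  invisible(cfg)
}

#' @export
print.algo_config <- function(x, ...) {
  cat("<algo_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write a classifier configuration as YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path File path.
#' @return `read_algo_config()` returns an [algo_config()];
#'   `write_algo_config()` returns `path` invisibly.
#' @export
read_algo_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(algo_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(algo_config, vals)
}

#' @rdname read_algo_config
#' @param config An [algo_config()].
#' @export
write_algo_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
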