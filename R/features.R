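#' Remove the per-axis offset (mean acceleration)
#'
#' Subtracts the arithmetic mean from each acceleration axis. Offset removal
#' feeds the movement-intensity (windowed SD) features only; tilt angles are
#' computed from the gravity-bearing (non-offset-removed) signal, since the
#' arccos tilt formulas are meaningless once the gravity component is
#' subtracted.
#'
#' @param rec A [triaxial_recording()].
#' @return A [triaxial_recording()] with zero-mean axes.
#' @export
remove_offset <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  triaxial_recording(rec$timestamps,
                     rec$ax - mean(rec$ax),
                     rec$ay - mean(rec$ay),
                     rec$az - mean(rec$az),
                     nominal_rate = rec$nominal_rate)
}

#' Windowed feature series for bout classification
#'
#' Transforms a uniform recording into the per-window features the classifier
#' operates on. The three axes are low-pass filtered (zero-phase, order 2,
#' 17 Hz by default); the recording is then cut into non-overlapping windows
#' of `window_s` seconds (0.1 s, i.e. 10 samples at 100 Hz; a trailing
#' partial window is dropped). Per window:
#'
#' * `std_ax`, `std_ay`, `std_az`: standard deviations of the offset-removed
#'   filtered axes (the SD is invariant to the mean shift, so these equal the
#'   SDs of the filtered axes); `std_sum` is their sum, and
#'   `std_sum_filtered` is `std_sum` low-passed at `std_cutoff_hz` (1 Hz) at
#'   the window rate.
#' * `tilt_vt`, `tilt_ml`, `tilt_ap`: tilt angles (degrees) of each device
#'   axis against the total acceleration vector,
#'   `acos(x / sqrt(ax^2 + ay^2 + az^2)) * 180 / pi`, computed from the
#'   window-mean filtered (gravity-bearing) acceleration vector;
#'   `tilt_*_filtered` are the 0.25 Hz low-passed versions, clipped to
#'   `[0, 180]`.
#'
#' A window whose mean acceleration vector has (near-)zero magnitude carries
#' the previous window's tilt angles (90 degrees if it is the first window).
#' When the recording yields too few windows to support the secondary
#' filters' edge padding, the filtered series equal the raw ones.
#'
#' @param rec A uniform [triaxial_recording()] (see [resample_uniform()]).
#' @param config An [algo_config()].
#' @return An object of class `window_features`: a data frame with one row
#'   per window (`window_start_frame` is the 0-based sample index of the
#'   window start) and attributes `window_rate`, `sample_rate`, `t0`.
#' @export
window_features <- function(rec, config = algo_config()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  rate <- rec$nominal_rate
  if (!is_uniform(rec, rate, tol = 1e-6))
    stop("recording must be uniformly sampled; apply resample_uniform() first",
         call. = FALSE)
  wlen <- round(config$window_s * rate)
  n <- n_samples(rec)
  nw <- floor(n / wlen)
  if (nw < 1L)
    stop(sprintf("recording too short: %d samples, need at least %d (one window)",
                 n, wlen), call. = FALSE)
  ord <- config$filter_order

  fx <- lowpass_zero_phase(rec$ax, ord, config$accel_cutoff_hz, rate)
  fy <- lowpass_zero_phase(rec$ay, ord, config$accel_cutoff_hz, rate)
  fz <- lowpass_zero_phase(rec$az, ord, config$accel_cutoff_hz, rate)

  used <- nw * wlen
  dim3 <- function(v) matrix(v[seq_len(used)], nrow = wlen)
  mx <- dim3(fx); my <- dim3(fy); mz <- dim3(fz)

  col_sd <- function(m) {
    mu <- colMeans(m)
    v <- (colSums(m * m) - wlen * mu * mu) / (wlen - 1)
    sqrt(pmax(v, 0))
  }
  # SD path: offset removal shifts the mean only, leaving the SD unchanged
  std_ax <- col_sd(mx); std_ay <- col_sd(my); std_az <- col_sd(mz)
  std_sum <- std_ax + std_ay + std_az

  # tilt path: window-mean gravity-bearing vector
  gx <- colMeans(mx); gy <- colMeans(my); gz <- colMeans(mz)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  tilt_of <- function(comp) acos(pmin(pmax(comp / nrm, -1), 1)) * 180 / pi
  degenerate <- nrm < 1e-12
  nrm[degenerate] <- 1  # placeholder; overwritten below
  tilt_vt <- tilt_of(gx); tilt_ml <- tilt_of(gy); tilt_ap <- tilt_of(gz)
  if (any(degenerate)) {
    for (w in which(degenerate)) {
      if (w == 1L) {
        tilt_vt[w] <- 90; tilt_ml[w] <- 90; tilt_ap[w] <- 90
      } else {
        tilt_vt[w] <- tilt_vt[w - 1L]
        tilt_ml[w] <- tilt_ml[w - 1L]
        tilt_ap[w] <- tilt_ap[w - 1L]
      }
    }
  }

  wrate <- rate / wlen
  pad <- 3 * ord
  smooth <- function(x, cutoff) {
    if (length(x) <= pad) return(x)  # too short to pad: pass through
    lowpass_zero_phase(x, ord, cutoff, wrate)
  }
  clip180 <- function(x) pmin(pmax(x, 0), 180)

  out <- data.frame(
    window_start_frame = (seq_len(nw) - 1L) * wlen,
    std_ax = std_ax, std_ay = std_ay, std_az = std_az,
    std_sum = std_sum,
    std_sum_filtered = smooth(std_sum, config$std_cutoff_hz),
    tilt_vt = tilt_vt, tilt_ml = tilt_ml, tilt_ap = tilt_ap,
    tilt_vt_filtered = clip180(smooth(tilt_vt, config$tilt_cutoff_hz)),
    tilt_ml_filtered = clip180(smooth(tilt_ml, config$tilt_cutoff_hz)),
    tilt_ap_filtered = clip180(smooth(tilt_ap, config$tilt_cutoff_hz))
  )
  structure(out, class = c("window_features", "data.frame"),
            window_rate = wrate, sample_rate = rate,
            t0 = rec$timestamps[1])
}

#' Export a feature series to CSV (for debugging/inspection)
#'
#' @param wfs A [window_features()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_window_features <- function(wfs, path) {
  stopifnot(inherits(wfs, "window_features"))
  df <- as.data.frame(wfs)
  df <- cbind(window_start_s = attr(wfs, "t0") +
                df$window_start_frame / attr(wfs, "sample_rate"), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
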