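#' Read an AX6/OmGui-dialect CSV recording
#'
#' Reads a delimited-text accelerometer export with a timestamp column and
#' three acceleration columns in g, in the device-axis convention `ax`
#' vertical, `ay` mediolateral, `az` anterior-posterior. Timestamps are
#' either MATLAB fractional days (OmGui's "Fractional days (MATLAB)" export
#' option; 1 day = 86400 s) or plain seconds, selected by `dialect`; they are
#' converted to seconds relative to the first sample. Extra columns (e.g.
#' gyroscope channels) are tolerated and ignored. A header row is detected
#' automatically.
#'
#' @param path CSV file path.
#' @param dialect `"fractional_day"` (default) or `"seconds"`.
#' @param col_map Integer vector of length 4 giving the column positions of
#'   timestamp, ax, ay, az (default `1:4`). Use this (optionally with
#'   `axis_sign`) to remap exports whose column order or axis polarity
#'   differs.
#' @param axis_sign Numeric vector of length 3 of `+1`/`-1` applied to
#'   (ax, ay, az) after mapping.
#' @param nominal_rate Nominal sampling rate stored on the recording
#'   (default 100 Hz).
#' @return A [triaxial_recording()].
#' @export
read_ax6_csv <- function(path, dialect = c("fractional_day", "seconds"),
                         col_map = 1:4, axis_sign = c(1, 1, 1),
                         nominal_rate = 100) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(length(col_map) == 4L, length(axis_sign) == 3L,
            all(axis_sign %in% c(-1, 1)))
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path, call. = FALSE)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1]]))))
  df <- utils::read.table(path, sep = ",", header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("expected at least 4 columns (timestamp, ax, ay, az), found ",
         ncol(df), call. = FALSE)
  if (max(col_map) > ncol(df))
    stop("col_map refers to column ", max(col_map), " but file has only ",
         ncol(df), call. = FALSE)
  num <- lapply(col_map, function(j) suppressWarnings(as.numeric(df[[j]])))
  for (k in seq_along(num)) {
    bad <- which(is.na(num[[k]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column %d at data row %d of %s",
                   col_map[k], bad[1], path), call. = FALSE)
  }
  ts <- num[[1]]
  ts <- if (dialect == "fractional_day") (ts - ts[1]) * 86400 else ts - ts[1]
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    r <- which(diff(ts) <= 0)[1] + 1L
    stop(sprintf("timestamps not strictly increasing at data row %d of %s",
                 r, path), call. = FALSE)
  }
  triaxial_recording(ts,
                     axis_sign[1] * num[[2]],
                     axis_sign[2] * num[[3]],
                     axis_sign[3] * num[[4]],
                     nominal_rate = nominal_rate)
}

#' Write a recording as CSV
#'
#' Inverse of [read_ax6_csv()]: writes columns `timestamp,ax,ay,az` with a
#' header. With `dialect = "fractional_day"` timestamps are written as
#' MATLAB fractional days.
#'
#' @param rec A [triaxial_recording()].
#' @param path Output path.
#' @param dialect `"seconds"` (default) or `"fractional_day"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("seconds", "fractional_day")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "triaxial_recording"))
  ts <- if (dialect == "fractional_day") rec$timestamps / 86400 else rec$timestamps
  df <- data.frame(timestamp = format(ts, digits = 17, scientific = FALSE,
                                      trim = TRUE),
                   ax = format(rec$ax, digits = 17, trim = TRUE),
                   ay = format(rec$ay, digits = 17, trim = TRUE),
                   az = format(rec$az, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Interpolates each axis onto the uniform grid `t0, t0 + 1/rate, ...`
#' anchored at the first timestamp and clipped to the recorded span (no
#' extrapolation), using shape-preserving piecewise-cubic Hermite (pchip-type,
#' Fritsch-Carlson) interpolation — monotone between knots, no overshoot.
#' This compensates the device's real-time clock drift before windowing.
#'
#' @param rec A [triaxial_recording()] with at least 2 samples.
#' @param target_rate Target rate in Hz (default: the recording's nominal
#'   rate).
#' @return A uniform [triaxial_recording()] at `target_rate`.
#' @export
resample_uniform <- function(rec, target_rate = rec$nominal_rate) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a positive scalar (Hz)", call. = FALSE)
  n <- n_samples(rec)
  if (n < 2L) stop("resampling needs at least 2 samples", call. = FALSE)
  t0 <- rec$timestamps[1]
  span <- rec$timestamps[n] - t0
  grid <- t0 + seq(0, floor(span * target_rate)) / target_rate
  # guard against floating-point spill past the last knot
  grid[grid > rec$timestamps[n]] <- rec$timestamps[n]
  hermite <- function(y)
    stats::splinefun(rec$timestamps, y, method = "monoH.FC")(grid)
  triaxial_recording(
    t0 + (seq_along(grid) - 1) / target_rate,
    hermite(rec$ax), hermite(rec$ay), hermite(rec$az),
    nominal_rate = target_rate
  )
}

#' Locate synchronisation taps
#'
#' Finds the short high-frequency spikes produced by tapping the device (used
#' to align the sensor timeline with a reference recording). The summed
#' per-window (0.1 s) standard deviation is scanned for local maxima
#' exceeding `threshold_multiple` times its median; a run of `expected`
#' spikes whose successive spacings match `spacing` within `tolerance` is
#' returned.
#'
#' @param rec A uniform [triaxial_recording()].
#' @param expected Number of taps to find (default 3).
#' @param spacing Nominal inter-tap interval in seconds (default 1).
#' @param tolerance Allowed deviation of each spacing in seconds
#'   (default 0.3).
#' @param threshold_multiple Spike threshold as a multiple of the median
#'   summed windowed SD (default 8).
#' @param window_s Analysis window in seconds (default 0.1).
#' @return Numeric vector of `expected` tap times (s, window centres).
#' @export
detect_sync_taps <- function(rec, expected = 3, spacing = 1, tolerance = 0.3,
                             threshold_multiple = 8, window_s = 0.1) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!is_uniform(rec, tol = 1e-6))
    stop("tap detection requires a uniformly resampled recording", call. = FALSE)
  rate <- rec$nominal_rate
  wlen <- max(2L, round(window_s * rate))
  n <- n_samples(rec)
  nw <- floor(n / wlen)
  if (nw < 3L) stop("recording too short for tap detection", call. = FALSE)
  used <- nw * wlen
  col_sd3 <- function(v) {
    m <- matrix(v[seq_len(used)], nrow = wlen)
    mu <- colMeans(m)
    sqrt(pmax((colSums(m * m) - wlen * mu * mu) / (wlen - 1), 0))
  }
  ss <- col_sd3(rec$ax) + col_sd3(rec$ay) + col_sd3(rec$az)
  # floor the median so a perfectly quiet signal cannot make every
  # fluctuation a "spike"
  thr <- threshold_multiple * max(median(ss), 1e-4)
  is_peak <- ss >= thr &
    ss >= c(-Inf, ss[-nw]) &
    ss >= c(ss[-1], -Inf)
  peaks <- which(is_peak)
  # collapse peaks in adjacent windows (one tap can straddle a boundary)
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > 1L)
    grp <- cumsum(keep)
    peaks <- vapply(split(peaks, grp), function(p) p[which.max(ss[p])], 0L)
  }
  times <- rec$timestamps[1] + (peaks - 0.5) * wlen / rate
  if (length(times) < expected)
    stop(sprintf("sync-tap detection failed: %d qualifying spike(s) found, %d expected",
                 length(times), expected), call. = FALSE)
  # search for a chain of `expected` spikes with matching spacings
  for (i in seq_len(length(times) - expected + 1L)) {
    chain <- times[i]
    last <- times[i]
    for (j in which(times > last)) {
      if (length(chain) == expected) break
      gap <- times[j] - last
      if (abs(gap - spacing) <= tolerance) {
        chain <- c(chain, times[j]); last <- times[j]
      } else if (gap > spacing + tolerance) break
    }
    if (length(chain) == expected) return(chain)
  }
  stop(sprintf("sync-tap detection failed: %d spike(s) found but no run of %d matches spacing %g s within %g s",
               length(times), expected, spacing, tolerance), call. = FALSE)
}

#' Read a labelled-interval annotation table
#'
#' Reads a CSV with columns `start_s`, `end_s`, `label` (three-class set:
#' sitting, lying, upright) into an [annotation_track()]. Such tables stand
#' in for video-observation exports and are also written by the simulator.
#'
#' @param path CSV path.
#' @param source Provenance tag (default `"file"`).
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, source = "file") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns start_s, end_s, label",
         call. = FALSE)
  annotation_track(df, source = source)
}

#' Write bouts or annotations as CSV
#'
#' Writes the standard interval table (`start_s,end_s,label`). Accepts a
#' [bout_sequence()] or an [annotation_track()]; round-trip stable with
#' [read_annotations()].
#'
#' @param x A [bout_sequence()] or [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(x, path) {
  df <- interval_df(x)
  df$start_s <- format(df$start_s, digits = 17, trim = TRUE)
  df$end_s <- format(df$end_s, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
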