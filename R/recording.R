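#' Triaxial accelerometer recording
#'
#' Container for a timestamped triaxial acceleration series in the lower-back
#' device convention: `ax` vertical, `ay` mediolateral, `az`
#' anterior-posterior, all in g. Timestamps are seconds since the start of the
#' recording and must be strictly increasing; they need not be uniform until
#' [resample_uniform()] has been applied.
#'
#' @param timestamps Numeric vector, seconds since recording start, strictly
#'   increasing.
#' @param ax,ay,az Numeric vectors of acceleration (g) along the vertical,
#'   mediolateral and anterior-posterior device axes.
#' @param nominal_rate Nominal sampling rate in Hz (default 100).
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(timestamps, ax, ay, az, nominal_rate = 100) {
  timestamps <- as.numeric(timestamps)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(timestamps)
  if (n < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("timestamps, ax, ay, az must have equal length", call. = FALSE)
  if (anyNA(timestamps) || anyNA(ax) || anyNA(ay) || anyNA(az))
    stop("recording contains missing values", call. = FALSE)
  if (n > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0)
    stop("nominal_rate must be a positive scalar", call. = FALSE)
  structure(
    list(timestamps = timestamps, ax = ax, ay = ay, az = az,
         nominal_rate = nominal_rate),
    class = "triaxial_recording"
  )
}

#' Number of samples in a recording
#' @param rec A [triaxial_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$timestamps)

#' Is a recording on a uniform grid?
#'
#' @param rec A [triaxial_recording()].
#' @param rate Grid rate to test against (Hz); defaults to the recording's
#'   nominal rate.
#' @param tol Tolerance on successive timestamp differences (s).
#' @return Logical.
#' @export
is_uniform <- function(rec, rate = rec$nominal_rate, tol = 1e-9) {
  n <- n_samples(rec)
  if (n < 2L) return(TRUE)
  all(abs(diff(rec$timestamps) - 1 / rate) <= tol)
}

#' @export
print.triaxial_recording <- function(x, ...) {
  n <- n_samples(x)
  span <- if (n > 1) x$timestamps[n] - x$timestamps[1] else 0
  cat(sprintf(
    "<triaxial_recording> %d samples, %.2f s span, nominal %g Hz (%s)\n",
    n, span, x$nominal_rate,
    if (is_uniform(x)) "uniform" else "non-uniform"))
  invisible(x)
}

#' Labelled activity intervals
#'
#' An ordered set of non-overlapping, half-open `[start_s, end_s)` intervals
#' labelled with the three-class activity set (sitting, lying, upright). Used
#' both for reference annotations (e.g. derived from video observation) and
#' for simulator ground truth.
#'
#' @param intervals Data frame with columns `start_s`, `end_s`, `label`.
#' @param source Free-text provenance tag, e.g. `"video"` or `"simulator"`.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(intervals, source = "unknown") {
  intervals <- as.data.frame(intervals)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(intervals)))
    stop("intervals must have columns start_s, end_s, label", call. = FALSE)
  intervals <- intervals[, need]
  intervals$start_s <- as.numeric(intervals$start_s)
  intervals$end_s <- as.numeric(intervals$end_s)
  intervals$label <- as.character(intervals$label)
  bad <- setdiff(unique(intervals$label), .sb_labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected sitting/lying/upright)", call. = FALSE)
  if (any(intervals$start_s >= intervals$end_s))
    stop("intervals must satisfy start_s < end_s", call. = FALSE)
  o <- order(intervals$start_s)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 1L &&
      any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)] - 1e-12))
    stop("intervals must not overlap", call. = FALSE)
  structure(list(intervals = intervals, source = source),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("<annotation_track> %d intervals, %.2f-%.2f s, source: %s\n",
              nrow(iv), min(iv$start_s), max(iv$end_s), x$source))
  tab <- tapply(iv$end_s - iv$start_s, iv$label, sum)
  for (lab in names(tab)) cat(sprintf("  %-8s %8.2f s\n", lab, tab[[lab]]))
  invisible(x)
}

#' Classified bout sequence
#'
#' The classifier's output: an ordered, contiguous tiling of the analysed
#' window range by labelled bouts. Frames are 0.1 s window indices (half-open
#' `[start_frame, end_frame)`); seconds are relative to the recording start.
#' Adjacent bouts always carry distinct labels (same-label neighbours are
#' merged on construction, combining their duration-weighted mean
#' anterior-posterior tilt).
#'
#' @param bouts Data frame with columns `start_frame`, `end_frame`, `label`
#'   and optionally `mean_tilt_ap` (degrees).
#' @param window_rate Windows per second (default 10).
#' @param t0 Time (s) of the first window's start, used to derive `start_s`
#'   and `end_s`.
#' @return An object of class `bout_sequence`: a data frame with columns
#'   `start_frame`, `end_frame`, `start_s`, `end_s`, `label`, `mean_tilt_ap`.
#' @export
bout_sequence <- function(bouts, window_rate = 10, t0 = 0) {
  bouts <- as.data.frame(bouts)
  if (!all(c("start_frame", "end_frame", "label") %in% names(bouts)))
    stop("bouts must have columns start_frame, end_frame, label", call. = FALSE)
  if (nrow(bouts) == 0L) stop("bout sequence must be non-empty", call. = FALSE)
  if (is.null(bouts$mean_tilt_ap)) bouts$mean_tilt_ap <- NA_real_
  bouts$label <- as.character(bouts$label)
  bad <- setdiff(unique(bouts$label), .sb_labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(bouts$start_frame >= bouts$end_frame))
    stop("bouts must satisfy start_frame < end_frame", call. = FALSE)
  o <- order(bouts$start_frame)
  bouts <- bouts[o, , drop = FALSE]
  if (nrow(bouts) > 1L &&
      any(bouts$start_frame[-1] != bouts$end_frame[-nrow(bouts)]))
    stop("bouts must tile the window range contiguously", call. = FALSE)

  # merge adjacent same-label bouts
  grp <- cumsum(c(TRUE, bouts$label[-1] != bouts$label[-nrow(bouts)]))
  if (any(duplicated(grp))) {
    dur <- bouts$end_frame - bouts$start_frame
    merged <- data.frame(
      start_frame = tapply(bouts$start_frame, grp, min),
      end_frame = tapply(bouts$end_frame, grp, max),
      label = tapply(bouts$label, grp, function(l) l[1]),
      mean_tilt_ap = tapply(seq_len(nrow(bouts)), grp, function(i)
        sum(bouts$mean_tilt_ap[i] * dur[i]) / sum(dur[i]))
    )
    bouts <- merged
  }
  bouts$start_s <- t0 + bouts$start_frame / window_rate
  bouts$end_s <- t0 + bouts$end_frame / window_rate
  bouts <- bouts[, c("start_frame", "end_frame", "start_s", "end_s",
                     "label", "mean_tilt_ap")]
  rownames(bouts) <- NULL
  structure(bouts, class = c("bout_sequence", "data.frame"),
            window_rate = window_rate, t0 = t0)
}

#' Convert a bout sequence to an annotation track
#' @param bouts A [bout_sequence()].
#' @param source Provenance tag for the resulting track.
#' @return An [annotation_track()].
#' @export
as_annotation_track <- function(bouts, source = "algorithm") {
  if (inherits(bouts, "annotation_track")) return(bouts)
  stopifnot(inherits(bouts, "bout_sequence"))
  annotation_track(
    data.frame(start_s = bouts$start_s, end_s = bouts$end_s,
               label = bouts$label),
    source = source)
}

#' @export
print.bout_sequence <- function(x, ...) {
  cat(sprintf("<bout_sequence> %d bouts, %.2f-%.2f s\n",
              nrow(x), min(x$start_s), max(x$end_s)))
  print(as.data.frame(x), ...)
  invisible(x)
}

# uniform interval representation used by the agreement module
interval_df <- function(x) {
  if (inherits(x, "annotation_track")) return(x$intervals)
  if (inherits(x, "bout_sequence"))
    return(data.frame(start_s = x$start_s, end_s = x$end_s, label = x$label))
  x <- as.data.frame(x)
  stopifnot(all(c("start_s", "end_s", "label") %in% names(x)))
  x[, c("start_s", "end_s", "label")]
}
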