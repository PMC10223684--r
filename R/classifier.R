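#' Profile a recording as upright-likely or not
#'
#' Decides, from the whole-recording means of the filtered tilt angles,
#' whether the wearer is likely to spend more time in upright activities.
#' The test is `ceiling(mean) >= threshold` on all three tilt channels
#' (vertical 150, mediolateral 90, anterior-posterior 90 degrees by
#' default); the ceiling makes the comparison act on the smallest integer not
#' below the mean. An upright-likely profile selects the movement-intensity
#' branch of [detect_upright_windows()].
#'
#' @param wfs A [window_features()] series.
#' @param config An [algo_config()].
#' @return An object of class `candidate_profile`: list with
#'   `upright_likely`, the three mean filtered tilts, and
#'   `mean_std_sum_filtered`.
#' @export
profile_candidate <- function(wfs, config = algo_config()) {
  stopifnot(inherits(wfs, "window_features"), nrow(wfs) >= 1L)
  m_vt <- mean(wfs$tilt_vt_filtered)
  m_ml <- mean(wfs$tilt_ml_filtered)
  m_ap <- mean(wfs$tilt_ap_filtered)
  upright_likely <-
    ceiling(m_vt) >= config$vt_upright_profile_deg &&
    ceiling(m_ml) >= config$ml_upright_profile_deg &&
    ceiling(m_ap) >= config$ap_upright_profile_deg
  structure(
    list(upright_likely = upright_likely,
         mean_tilt_vt_filtered = m_vt,
         mean_tilt_ml_filtered = m_ml,
         mean_tilt_ap_filtered = m_ap,
         mean_std_sum_filtered = mean(wfs$std_sum_filtered)),
    class = "candidate_profile")
}

#' @export
print.candidate_profile <- function(x, ...) {
  cat(sprintf(
    "<candidate_profile> upright_likely: %s\n  mean tilt VT/ML/AP (filtered): %.1f / %.1f / %.1f deg\n  mean std_sum_filtered: %.4f g\n",
    x$upright_likely, x$mean_tilt_vt_filtered, x$mean_tilt_ml_filtered,
    x$mean_tilt_ap_filtered, x$mean_std_sum_filtered))
  invisible(x)
}

#' Flag windows as potential upright movement
#'
#' For an upright-likely profile, a window is flagged when its filtered
#' summed SD reaches the whole-recording mean of that channel (movement
#' intensity); in the default `"gated"` mode the flag additionally requires
#' the per-window tilt test (vertical tilt >= 140 and anterior-posterior
#' tilt >= 75 degrees), which confirms upright posture and keeps still
#' standing detectable. `"strict"` mode applies the movement-intensity test
#' alone. For a non-upright-likely profile, the per-window tilt test alone
#' decides.
#'
#' @param wfs A [window_features()] series.
#' @param profile The [profile_candidate()] result for the same series.
#' @param config An [algo_config()].
#' @return Logical vector, one flag per window.
#' @export
detect_upright_windows <- function(wfs, profile, config = algo_config()) {
  stopifnot(inherits(wfs, "window_features"),
            inherits(profile, "candidate_profile"))
  tilt_ok <- wfs$tilt_vt_filtered >= config$vt_upright_window_deg &
    wfs$tilt_ap_filtered >= config$ap_upright_window_deg
  if (profile$upright_likely) {
    move_ok <- wfs$std_sum_filtered >= mean(wfs$std_sum_filtered)
    if (config$mode == "strict") move_ok else move_ok & tilt_ok
  } else {
    tilt_ok
  }
}

#' Cut a flag series into alternating candidate/non-upright segments
#'
#' Maximal runs of `TRUE` become potential upright bouts; the gaps between
#' them (including leading/trailing runs of `FALSE`) become non-upright
#' segments. Indices are half-open window frames.
#'
#' @param flags Logical vector from [detect_upright_windows()].
#' @return Data frame with columns `start_frame`, `end_frame` (half-open
#'   window indices) and `candidate` (logical).
#' @export
extract_bouts <- function(flags) {
  stopifnot(is.logical(flags), length(flags) >= 1L, !anyNA(flags))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  data.frame(start_frame = c(0L, ends[-length(ends)]),
             end_frame = ends,
             candidate = r$values)
}

#' Label segments as sitting, lying or upright
#'
#' Candidate (potential upright) segments are relabelled by their mean
#' filtered anterior-posterior tilt: below `ap_lying_fixed_deg` (40) ->
#' lying; below `ap_sitting_fixed_deg` (80) -> sitting; otherwise confirmed
#' upright. Each non-upright segment is labelled against the preceding
#' confirmed upright bout: mean tilt below the upright bout's mean divided by
#' `lying_ratio` (2.5) -> lying; below the upright bout's mean -> sitting;
#' otherwise upright. A non-upright segment with no preceding confirmed
#' upright bout falls back to the fixed thresholds. Adjacent same-label bouts
#' are merged.
#'
#' @param segments Output of [extract_bouts()].
#' @param wfs The [window_features()] series the flags were derived from.
#' @param config An [algo_config()].
#' @return A [bout_sequence()].
#' @export
label_bouts <- function(segments, wfs, config = algo_config()) {
  stopifnot(inherits(wfs, "window_features"), nrow(segments) >= 1L)
  ap <- wfs$tilt_ap_filtered
  fixed_label <- function(m) {
    if (m < config$ap_lying_fixed_deg) "lying"
    else if (m < config$ap_sitting_fixed_deg) "sitting"
    else "upright"
  }
  labels <- character(nrow(segments))
  mean_ap <- numeric(nrow(segments))
  preceding_upright_ap <- NA_real_
  for (i in seq_len(nrow(segments))) {
    idx <- (segments$start_frame[i] + 1L):segments$end_frame[i]
    m <- mean(ap[idx])
    mean_ap[i] <- m
    if (segments$candidate[i] || is.na(preceding_upright_ap)) {
      lab <- fixed_label(m)
    } else {
      lab <- if (m < preceding_upright_ap / config$lying_ratio) "lying"
      else if (m < preceding_upright_ap) "sitting"
      else "upright"
    }
    labels[i] <- lab
    if (lab == "upright") preceding_upright_ap <- m
  }
  df <- data.frame(start_frame = segments$start_frame,
                   end_frame = segments$end_frame,
                   label = labels, mean_tilt_ap = mean_ap)
  wrate <- attr(wfs, "window_rate")
  bouts <- bout_sequence(df, window_rate = wrate, t0 = attr(wfs, "t0"))
  if (config$min_bout_s > 0) {
    bouts <- enforce_min_bout(bouts, config$min_bout_s, wrate,
                              attr(wfs, "t0"))
  }
  bouts
}

# absorb bouts shorter than min_s into the longer adjacent neighbour,
# shortest first
enforce_min_bout <- function(bouts, min_s, window_rate, t0) {
  df <- as.data.frame(bouts)
  repeat {
    dur <- df$end_frame - df$start_frame
    short <- which(dur / window_rate < min_s - 1e-9)
    if (!length(short) || nrow(df) == 1L) break
    i <- short[which.min(dur[short])]
    left <- if (i > 1L) dur[i - 1L] else -1L
    right <- if (i < nrow(df)) dur[i + 1L] else -1L
    j <- if (left >= right) i - 1L else i + 1L
    df$label[i] <- df$label[j]
    grp <- cumsum(c(TRUE, df$label[-1] != df$label[-nrow(df)]))
    dur_all <- df$end_frame - df$start_frame
    df <- data.frame(
      start_frame = as.vector(tapply(df$start_frame, grp, min)),
      end_frame = as.vector(tapply(df$end_frame, grp, max)),
      label = as.vector(tapply(df$label, grp, function(l) l[1])),
      mean_tilt_ap = as.vector(tapply(seq_len(nrow(df)), grp, function(k)
        sum(df$mean_tilt_ap[k] * dur_all[k]) / sum(dur_all[k])))
    )
  }
  bout_sequence(df, window_rate = window_rate, t0 = t0)
}

#' Classify a recording into sitting, lying and upright bouts
#'
#' Full pipeline: uniform resampling (if needed), windowed feature
#' extraction, candidate profiling, per-window upright detection, run-length
#' segmentation and semi-adaptive labelling. Deterministic for a fixed input
#' and configuration.
#'
#' @param rec A [triaxial_recording()] (raw or already resampled).
#' @param config An [algo_config()].
#' @return A [bout_sequence()] with attributes `profile` (the
#'   [profile_candidate()] result) and `config`.
#' @export
classify_recording <- function(rec, config = algo_config()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!is_uniform(rec, config$target_rate_hz, tol = 1e-9))
    rec <- resample_uniform(rec, config$target_rate_hz)
  wfs <- window_features(rec, config)
  profile <- profile_candidate(wfs, config)
  flags <- detect_upright_windows(wfs, profile, config)
  segments <- extract_bouts(flags)
  bouts <- label_bouts(segments, wfs, config)
  attr(bouts, "profile") <- profile
  attr(bouts, "config") <- config
  bouts
}
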