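default_orientations <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(
    # device on the lower back (L5), ax vertical: at rest the accelerometer
    # reads +1 g opposite gravity along whichever axis points up
    standing = c(-1, 0, 0),                    # VT 180, AP 90 deg
    walking = unit(c(-0.996, 0, 0.0872)),      # ~5 deg forward trunk lean
    sitting = unit(c(-0.707, 0, 0.707)),       # VT 135, AP 45 deg
    lying = unit(c(-0.342, 0, 0.940))          # supine: AP ~20 deg
  )
}

# angle (deg) between axis i of a device-frame vector and the vector itself
tilt_deg <- function(v, i) {
  acos(pmin(pmax(v[i] / sqrt(sum(v^2)), -1), 1)) * 180 / pi
}

#' Define a simulation script
#'
#' An activity script for the signal simulator: an ordered list of posture
#' segments plus the physical parameters of the rendered signal. Ground
#' truth collapses standing and walking to "upright".
#'
#' Default orientations place the device on the lower back with the vertical
#' axis along gravity when standing; they are chosen so the default postures
#' are separable by the classifier's thresholds (standing vertical tilt
#' >= 150, sitting anterior-posterior tilt in (40, 80), lying
#' anterior-posterior tilt < 40 degrees), which is asserted at construction.
#'
#' @param segments Data frame (or list coercible to one) with columns
#'   `label` (sitting/lying/standing/walking) and `duration_s` (> 0);
#'   optional column `orientation` (list of unit 3-vectors overriding the
#'   per-posture default).
#' @param orientations Named list of unit gravity vectors (device axes, g)
#'   per posture label.
#' @param still_noise_sd SD of Gaussian axis noise in still postures (g,
#'   default 0.01).
#' @param walk_noise_sd SD of broadband Gaussian axis noise while walking
#'   (g, default 0.08).
#' @param gait_hz,gait_amp_g Frequency (Hz) and vertical amplitude (g) of
#'   the sinusoidal gait component added while walking (defaults 2, 0.15).
#' @param transition_s Duration of smooth (slerp) postural transitions
#'   centred on segment boundaries (s, default 2).
#' @param tap_times Times (s) of synchronisation taps to inject.
#' @param timestamp_jitter_sd SD of Gaussian timestamp jitter (s, default
#'   0.001), emulating clock drift; 0 gives uniform stamps.
#' @param sample_rate Nominal rate (Hz, default 100).
#' @param seed Default RNG seed used by [simulate_recording()].
#' @return An object of class `simulation_script`.
#' @export
simulation_script <- function(segments,
                              orientations = default_orientations(),
                              still_noise_sd = 0.01,
                              walk_noise_sd = 0.08,
                              gait_hz = 2,
                              gait_amp_g = 0.15,
                              transition_s = 2,
                              tap_times = numeric(0),
                              timestamp_jitter_sd = 0.001,
                              sample_rate = 100,
                              seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("label", "duration_s") %in% names(segments)),
            nrow(segments) >= 1L)
  segments$label <- as.character(segments$label)
  bad <- setdiff(unique(segments$label), .sb_sim_labels)
  if (length(bad))
    stop("unknown posture label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(segments$duration_s <= 0))
    stop("segment durations must be positive", call. = FALSE)
  for (nm in names(orientations)) {
    v <- orientations[[nm]]
    if (length(v) != 3L || abs(sqrt(sum(v^2)) - 1) > 1e-6)
      stop("orientation for '", nm, "' must be a unit 3-vector", call. = FALSE)
  }
  miss <- setdiff(unique(segments$label), names(orientations))
  if (length(miss))
    stop("no orientation for posture(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (still_noise_sd < 0 || walk_noise_sd < 0 || transition_s < 0 ||
      timestamp_jitter_sd < 0 || sample_rate <= 0)
    stop("noise, transition, jitter and rate parameters must be non-negative (rate positive)",
         call. = FALSE)
  # the simulated postures must be separable by the classifier's thresholds
  if ("standing" %in% names(orientations) &&
      tilt_deg(orientations$standing, 1) < 150)
    stop("standing orientation must have vertical tilt >= 150 degrees",
         call. = FALSE)
  if ("sitting" %in% names(orientations)) {
    ap <- tilt_deg(orientations$sitting, 3)
    if (ap <= 40 || ap >= 80)
      stop("sitting orientation must have anterior-posterior tilt in (40, 80) degrees",
           call. = FALSE)
  }
  if ("lying" %in% names(orientations) &&
      tilt_deg(orientations$lying, 3) >= 40)
    stop("lying orientation must have anterior-posterior tilt < 40 degrees",
         call. = FALSE)
  structure(
    list(segments = segments[, intersect(c("label", "duration_s", "orientation"),
                                         names(segments)), drop = FALSE],
         orientations = orientations,
         still_noise_sd = still_noise_sd, walk_noise_sd = walk_noise_sd,
         gait_hz = gait_hz, gait_amp_g = gait_amp_g,
         transition_s = transition_s, tap_times = tap_times,
         timestamp_jitter_sd = timestamp_jitter_sd,
         sample_rate = sample_rate, seed = seed),
    class = "simulation_script")
}

#' @export
print.simulation_script <- function(x, ...) {
  cat(sprintf("<simulation_script> %d segments, %.0f s total, %g Hz, %d tap(s)\n",
              nrow(x$segments), sum(x$segments$duration_s), x$sample_rate,
              length(x$tap_times)))
  print(x$segments[, c("label", "duration_s")], row.names = FALSE)
  invisible(x)
}

#' The scripted in-home validation protocol
#'
#' The prescribed activity sequence used for scripted validation, bracketed
#' by three synchronisation taps at one-second intervals at either end
#' (injected during 5 s standing lead-in/lead-out segments): lounge-chair sit
#' 60 s; walk to the dining area and sit 60 s; walk to the bedroom and lie
#' supine 60 s; sit on the bed edge 3 s then stand 60 s; three walks between
#' dining area and bedroom and back to the lounge; lounge sit 60 s; quiet
#' stand 60 s. Walk durations are not prescribed ("comfortable pace"); this
#' script uses 15 s for direct walks and 20 s for the turn-back walks.
#'
#' @param ... Overrides passed on to [simulation_script()] (noise levels,
#'   orientations, seed, ...).
#' @return A [simulation_script()].
#' @export
scripted_protocol <- function(...) {
  segs <- data.frame(
    label = c("standing",                      # lead-in, taps
              "sitting",                       # (a) lounge chair
              "walking", "sitting",            # (b) dining chair
              "walking", "lying",              # (c) supine on bed
              "sitting", "standing",           # (d) bed edge 3 s, stand
              "walking",                       # (e) to dining area
              "walking",                       # (f) back to bedroom
              "walking",                       # (g) back to lounge
              "sitting",                       # (h) lounge chair
              "standing",                      # (i) quiet standing
              "standing"),                     # lead-out, taps
    duration_s = c(5, 60, 15, 60, 15, 60, 3, 60, 15, 20, 20, 60, 60, 5)
  )
  total <- sum(segs$duration_s)
  simulation_script(segs,
                    tap_times = c(1, 2, 3, total - 4, total - 3, total - 2),
                    ...)
}

# spherical interpolation between unit vectors
slerp <- function(u, v, s) {
  d <- pmin(pmax(sum(u * v), -1), 1)
  w <- acos(d)
  if (w < 1e-9) return(matrix(rep(u, each = length(s)), ncol = 3))
  (outer(sin((1 - s) * w), u) + outer(sin(s * w), v)) / sin(w)
}

#' Render a simulation script as a recording plus ground truth
#'
#' Generates the triaxial signal segment by segment: the posture's unit
#' gravity vector plus Gaussian axis noise; walking segments additionally
#' carry a sinusoidal gait component (vertical, with a quadrature
#' anterior-posterior component at 40% amplitude) so their windowed SD
#' separates them from still postures. Orientations are slerp-interpolated
#' over `transition_s` windows centred on segment boundaries; taps are
#' injected as 0.05 s high-amplitude triphasic spikes; timestamps are
#' jittered (non-uniform) when `timestamp_jitter_sd > 0`. The ground truth
#' assigns each boundary to the scripted time (transition time split equally
#' between the adjacent segments) and collapses standing/walking to
#' "upright".
#'
#' @param script A [simulation_script()].
#' @param seed RNG seed (default: the script's seed). The same script and
#'   seed give a bit-identical recording.
#' @return List with `recording` (a [triaxial_recording()]) and `truth` (an
#'   [annotation_track()], source `"simulator"`).
#' @export
simulate_recording <- function(script, seed = script$seed) {
  stopifnot(inherits(script, "simulation_script"))
  fs <- script$sample_rate
  durs <- script$segments$duration_s
  labs <- script$segments$label
  bounds <- cumsum(durs)            # segment end times
  total <- bounds[length(bounds)]
  n <- round(total * fs)
  t <- (0:(n - 1)) / fs

  seg_of <- findInterval(t, c(0, bounds[-length(bounds)]))
  ori <- matrix(0, n, 3)
  for (i in seq_along(labs)) {
    o <- if (!is.null(script$segments$orientation) &&
             !is.null(script$segments$orientation[[i]]))
      script$segments$orientation[[i]] else script$orientations[[labs[i]]]
    sel <- seg_of == i
    ori[sel, ] <- matrix(o, sum(sel), 3, byrow = TRUE)
  }
  # smooth postural transitions across interior boundaries
  tr <- script$transition_s
  if (tr > 0 && length(labs) > 1L) {
    for (i in seq_len(length(labs) - 1L)) {
      o1 <- ori[max(which(seg_of == i)), ]
      o2 <- ori[min(which(seg_of == i + 1L)), ]
      if (sum(abs(o1 - o2)) < 1e-12) next
      b <- bounds[i]
      sel <- which(t >= b - tr / 2 & t < b + tr / 2)
      if (!length(sel)) next
      s <- (t[sel] - (b - tr / 2)) / tr
      s <- s * s * (3 - 2 * s)      # smoothstep easing
      ori[sel, ] <- slerp(o1, o2, s)
    }
  }

  with_preserved_seed(seed, {
    walk <- labs[seg_of] == "walking"
    noise_sd <- ifelse(walk, script$walk_noise_sd, script$still_noise_sd)
    acc <- ori + matrix(rnorm(3 * n, 0, rep(noise_sd, 3)), n, 3)
    if (any(walk)) {
      phase <- 2 * pi * script$gait_hz * t
      acc[walk, 1] <- acc[walk, 1] + script$gait_amp_g * sin(phase[walk])
      acc[walk, 3] <- acc[walk, 3] +
        0.4 * script$gait_amp_g * sin(phase[walk] + pi / 2)
    }
    # synchronisation taps: short triphasic spikes, mostly anterior-posterior
    pulse <- c(1, -0.8, 0.6, -0.3, 0.1)
    for (tap in script$tap_times) {
      i0 <- round(tap * fs) + 1L
      idx <- i0:(i0 + length(pulse) - 1L)
      ok <- idx >= 1L & idx <= n
      acc[idx[ok], 3] <- acc[idx[ok], 3] + 4 * pulse[ok]
      acc[idx[ok], 1] <- acc[idx[ok], 1] + 2 * pulse[ok]
    }
    ts <- t
    if (script$timestamp_jitter_sd > 0) {
      ts <- t + rnorm(n, 0, script$timestamp_jitter_sd)
      ts[1] <- 0
      # jitter SD is far below the sample spacing, but guarantee monotonicity
      if (any(diff(ts) <= 0)) ts <- cummax(ts + (0:(n - 1)) * 1e-12)
    }
    rec <- triaxial_recording(ts, acc[, 1], acc[, 2], acc[, 3],
                              nominal_rate = fs)
    truth_lab <- ifelse(labs %in% c("standing", "walking"), "upright", labs)
    # collapse runs of identical truth labels into single bouts
    grp <- cumsum(c(TRUE, truth_lab[-1] != truth_lab[-length(truth_lab)]))
    starts <- c(0, bounds[-length(bounds)])
    truth <- annotation_track(
      data.frame(start_s = as.vector(tapply(starts, grp, min)),
                 end_s = as.vector(tapply(bounds, grp, max)),
                 label = as.vector(tapply(truth_lab, grp, function(l) l[1]))),
      source = "simulator")
    list(recording = rec, truth = truth)
  })
}

#' Read a simulation script from YAML
#'
#' The file mirrors [simulation_script()]: a `segments` list of
#' `{label, duration_s}` entries plus any of the scalar parameters;
#' orientations as named 3-vectors. The special form `protocol: scripted`
#' returns [scripted_protocol()] with any other keys as overrides.
#'
#' @param path YAML file path.
#' @return A [simulation_script()].
#' @export
read_simulation_script <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$protocol, "scripted")) {
    y$protocol <- NULL
    if (!is.null(y$orientations))
      y$orientations <- lapply(y$orientations, as.numeric)
    return(do.call(scripted_protocol, y))
  }
  if (is.null(y$segments))
    stop("script file must contain a 'segments' list or 'protocol: scripted'",
         call. = FALSE)
  segs <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(label = s$label, duration_s = as.numeric(s$duration_s))))
  y$segments <- NULL
  if (!is.null(y$orientations))
    y$orientations <- lapply(y$orientations, as.numeric)
  do.call(simulation_script, c(list(segments = segs), y))
}
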