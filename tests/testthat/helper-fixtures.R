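# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# constant-orientation recording, optional Gaussian noise
make_still_recording <- function(orientation, duration_s = 30, rate = 100,
                                 noise_sd = 0, seed = 1) {
  n <- round(duration_s * rate)
  t <- (0:(n - 1)) / rate
  if (noise_sd > 0) {
    set.seed(seed)
    eps <- matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  } else {
    eps <- matrix(0, n, 3)
  }
  triaxial_recording(t,
                     orientation[1] + eps[, 1],
                     orientation[2] + eps[, 2],
                     orientation[3] + eps[, 3],
                     nominal_rate = rate)
}

# forge a window_features object with chosen feature columns (defaults are
# neutral still-sitting-like values), for unit tests of the classifier rules
make_wfs <- function(n = 10, tilt_vt = 100, tilt_ml = 90, tilt_ap = 50,
                     std_sum = 0.01, window_rate = 10, t0 = 0) {
  rep_n <- function(v) rep_len(v, n)
  df <- data.frame(
    window_start_frame = (seq_len(n) - 1L) * 10L,
    std_ax = rep_n(std_sum) / 3, std_ay = rep_n(std_sum) / 3,
    std_az = rep_n(std_sum) / 3,
    std_sum = rep_n(std_sum), std_sum_filtered = rep_n(std_sum),
    tilt_vt = rep_n(tilt_vt), tilt_ml = rep_n(tilt_ml),
    tilt_ap = rep_n(tilt_ap),
    tilt_vt_filtered = rep_n(tilt_vt), tilt_ml_filtered = rep_n(tilt_ml),
    tilt_ap_filtered = rep_n(tilt_ap)
  )
  structure(df, class = c("window_features", "data.frame"),
            window_rate = window_rate, sample_rate = window_rate * 10,
            t0 = t0)
}

# random contiguous three-class label track over [0, span_s]
random_track <- function(span_s = 10, n_bouts = sample(2:6, 1),
                         labels = c("sitting", "lying", "upright")) {
  cuts <- sort(runif(n_bouts - 1, 0.5, span_s - 0.5))
  starts <- c(0, cuts); ends <- c(cuts, span_s)
  lab <- character(n_bouts)
  lab[1] <- sample(labels, 1)
  for (i in seq_len(n_bouts - 1)) {
    lab[i + 1] <- sample(setdiff(labels, lab[i]), 1)
  }
  annotation_track(data.frame(start_s = starts, end_s = ends, label = lab))
}

# a short random activity script (~2 min) for oracle-equivalence checks
random_script <- function(seed) {
  set.seed(seed)
  n_seg <- sample(3:6, 1)
  labs <- character(n_seg)
  labs[1] <- sample(c("sitting", "lying", "standing", "walking"), 1)
  for (i in seq_len(n_seg - 1))
    labs[i + 1] <- sample(setdiff(c("sitting", "lying", "standing", "walking"),
                                  labs[i]), 1)
  durs <- runif(n_seg, 10, 40)
  durs <- durs * (120 / sum(durs))
  simulation_script(data.frame(label = labs, duration_s = durs), seed = seed)
}
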