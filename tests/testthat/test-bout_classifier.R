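test_that("candidate profiling applies ceiling() to the mean tilts", {
  cfg <- algo_config()
  p <- profile_candidate(make_wfs(tilt_vt = 160.2, tilt_ml = 95, tilt_ap = 95), cfg)
  expect_true(p$upright_likely)
  p <- profile_candidate(make_wfs(tilt_vt = 145, tilt_ml = 95, tilt_ap = 95), cfg)
  expect_false(p$upright_likely)
  # ceiling(149.2) = 150 passes the 150-degree test
  p <- profile_candidate(make_wfs(tilt_vt = 149.2, tilt_ml = 90, tilt_ap = 90), cfg)
  expect_true(p$upright_likely)
  # all three thresholds must pass
  p <- profile_candidate(make_wfs(tilt_vt = 160, tilt_ml = 85, tilt_ap = 95), cfg)
  expect_false(p$upright_likely)
})

test_that("window-level upright detection follows the profile branch", {
  cfg <- algo_config()
  non_upright_profile <- profile_candidate(
    make_wfs(tilt_vt = 120, tilt_ml = 90, tilt_ap = 50), cfg)

  # non-upright-likely branch: tilt thresholds 140 / 75
  wfs <- make_wfs(n = 4, tilt_vt = 145, tilt_ap = 80)
  expect_true(all(detect_upright_windows(wfs, non_upright_profile, cfg)))
  wfs <- make_wfs(n = 4, tilt_vt = 90, tilt_ap = 20) # still lying
  expect_false(any(detect_upright_windows(wfs, non_upright_profile, cfg)))
  wfs <- make_wfs(n = 4, tilt_vt = 139.99, tilt_ap = 80)
  expect_false(any(detect_upright_windows(wfs, non_upright_profile, cfg)))

  # upright-likely branch: movement intensity against its whole-recording
  # mean, tilt-gated by default
  upright_profile <- profile_candidate(
    make_wfs(tilt_vt = 165, tilt_ml = 92, tilt_ap = 92), cfg)
  wfs <- make_wfs(n = 6, tilt_vt = 170, tilt_ap = 85,
                  std_sum = c(0.5, 0.5, 0.01, 0.01, 0.01, 0.01))
  flags <- detect_upright_windows(wfs, upright_profile, cfg)
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  # strict mode ignores the tilt gate; gated mode requires it
  wfs_lowtilt <- make_wfs(n = 6, tilt_vt = 100, tilt_ap = 30,
                          std_sum = c(0.5, 0.5, 0.01, 0.01, 0.01, 0.01))
  strict <- algo_config(mode = "strict")
  expect_equal(detect_upright_windows(wfs_lowtilt, upright_profile, strict),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(detect_upright_windows(wfs_lowtilt, upright_profile, cfg)))
})

test_that("run-length segmentation produces alternating half-open bouts", {
  seg <- extract_bouts(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(seg$start_frame, c(0, 3, 5))
  expect_equal(seg$end_frame, c(3, 5, 7))
  expect_equal(seg$candidate, c(TRUE, FALSE, TRUE))

  seg <- extract_bouts(rep(FALSE, 5))
  expect_equal(nrow(seg), 1)
  expect_false(seg$candidate)

  seg <- extract_bouts(rep(TRUE, 4))
  expect_equal(nrow(seg), 1)
  expect_true(seg$candidate)
})

test_that("bout labelling follows the fixed and adaptive tilt rules", {
  cfg <- algo_config()
  # candidate bout with mean AP 35 -> lying (fixed < 40)
  wfs <- make_wfs(n = 10, tilt_ap = 35)
  seg <- data.frame(start_frame = 0L, end_frame = 10L, candidate = TRUE)
  expect_equal(label_bouts(seg, wfs, cfg)$label, "lying")

  # non-upright segment mean AP 30 after an upright bout of mean AP 85:
  # 30 < 85 / 2.5 = 34 -> lying
  wfs <- make_wfs(n = 20, tilt_ap = c(rep(85, 10), rep(30, 10)))
  seg <- data.frame(start_frame = c(0L, 10L), end_frame = c(10L, 20L),
                    candidate = c(TRUE, FALSE))
  labels <- label_bouts(seg, wfs, cfg)$label
  expect_equal(labels, c("upright", "lying"))

  # mean AP 70 vs preceding 85: not < 34, but < 85 -> sitting
  wfs <- make_wfs(n = 20, tilt_ap = c(rep(85, 10), rep(70, 10)))
  labels <- label_bouts(seg, wfs, cfg)$label
  expect_equal(labels, c("upright", "sitting"))

  # mean AP 86 vs preceding 85 -> remains upright (and merges)
  wfs <- make_wfs(n = 20, tilt_ap = c(rep(85, 10), rep(86, 10)))
  bouts <- label_bouts(seg, wfs, cfg)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$label, "upright")
})

test_that("a still sitting-orientation recording yields one sitting bout", {
  # orientation (-0.94, 0.05, 0.33): anterior-posterior tilt ~70.7 degrees,
  # no upright bout anywhere, so the fixed 40/80 fallback applies
  rec <- make_still_recording(c(-0.94, 0.05, 0.33), duration_s = 60)
  bouts <- classify_recording(rec)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$label, "sitting")
  expect_equal(bouts$start_s, 0)
  expect_equal(bouts$end_s, 60)
  expect_equal(bouts$mean_tilt_ap, 70.68, tolerance = 0.05)
})

test_that("bouts tile the analysed span exactly and deterministically", {
  for (seed in c(2, 5)) {
    sim <- simulate_recording(random_script(seed))
    b1 <- classify_recording(sim$recording)
    b2 <- classify_recording(sim$recording)
    expect_identical(as.data.frame(b1), as.data.frame(b2))
    expect_equal(b1$start_frame[-1], b1$end_frame[-nrow(b1)])
    nw <- floor(n_samples(resample_uniform(sim$recording, 100)) / 10)
    expect_equal(sum(b1$end_frame - b1$start_frame), nw)
    expect_true(all(b1$label[-1] != b1$label[-nrow(b1)]))
  }
})

test_that("raising the fixed lying threshold only converts sitting to lying", {
  sim <- simulate_recording(scripted_protocol(seed = 3))
  rec <- resample_uniform(sim$recording, 100)
  wfs <- window_features(rec)
  lab_at <- function(thr) {
    cfg <- algo_config(ap_lying_fixed_deg = thr)
    b <- classify_recording(rec, cfg)
    lab <- character(nrow(wfs))
    for (i in seq_len(nrow(b))) lab[(b$start_frame[i] + 1):b$end_frame[i]] <- b$label[i]
    lab
  }
  low <- lab_at(30); high <- lab_at(55)
  changed <- which(low != high)
  expect_true(all(low[changed] == "sitting"))
  expect_true(all(high[changed] == "lying"))
})

test_that("label distribution is invariant to acceleration unit scaling", {
  sim <- simulate_recording(random_script(13))
  rec <- sim$recording
  rec_si <- triaxial_recording(rec$timestamps, rec$ax * 9.81, rec$ay * 9.81,
                               rec$az * 9.81, nominal_rate = rec$nominal_rate)
  b <- classify_recording(rec)
  b_si <- classify_recording(rec_si)
  expect_equal(b$label, b_si$label)
  expect_equal(b$start_frame, b_si$start_frame)
})

test_that("degenerate inputs are rejected with length errors", {
  expect_error(triaxial_recording(numeric(0), numeric(0), numeric(0),
                                  numeric(0)), "at least one sample")
  rec <- triaxial_recording((0:5) / 100, rep(1, 6), rep(0, 6), rep(0, 6))
  expect_error(classify_recording(rec), "too short")
})

test_that("a single-window recording classifies without secondary filtering", {
  rec <- make_still_recording(c(-0.94, 0.05, 0.33), duration_s = 0.1)
  bouts <- classify_recording(rec)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$label, "sitting")
})

test_that("minimum bout duration absorbs short bouts into neighbours", {
  sim <- simulate_recording(scripted_protocol(seed = 4))
  b <- classify_recording(sim$recording, algo_config(min_bout_s = 10))
  expect_true(all(b$end_s - b$start_s >= 10))
  expect_equal(b$start_frame[-1], b$end_frame[-nrow(b)])
})
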