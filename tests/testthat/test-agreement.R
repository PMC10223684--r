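test_that("frame confusion counts match hand-computed examples", {
  track <- annotation_track(data.frame(
    start_s = c(0, 30), end_s = c(30, 60), label = c("sitting", "upright")))
  cc <- frame_confusion(track, track, resolution = 0.01)
  expect_true(all(cc$fp == 0))
  expect_true(all(cc$fn == 0))
  expect_equal(attr(cc, "n_frames"), 6000)
  expect_equal(attr(cc, "n_agree"), 6000)

  pred <- annotation_track(data.frame(start_s = 0, end_s = 6, label = "sitting"))
  ref <- annotation_track(data.frame(start_s = c(0, 5), end_s = c(5, 6),
                                     label = c("sitting", "upright")))
  cc <- frame_confusion(pred, ref, resolution = 1)
  sit <- cc[cc$class == "sitting", ]
  expect_equal(sit$tp, 5)
  expect_equal(sit$fp, 1)
  expect_equal(sit$fn, 0)
  expect_equal(sit$tn, 0)

  expect_error(frame_confusion(
    pred, annotation_track(data.frame(start_s = 100, end_s = 110,
                                      label = "lying"))), "overlap")
})

test_that("frame confusion equals a brute-force per-frame loop", {
  set.seed(21)
  for (i in 1:25) {
    pred <- random_track()
    ref <- random_track()
    cc <- frame_confusion(pred, ref, resolution = 0.05)
    oracle <- brute_confusion(pred, ref, resolution = 0.05)
    for (cl in c("sitting", "lying", "upright")) {
      row <- cc[cc$class == cl, ]
      expect_equal(unname(unlist(row[c("tp", "fp", "tn", "fn")])),
                   unname(oracle[cl, c("tp", "fp", "tn", "fn")]))
    }
    # per-class TP totals add up to the agreeing frames
    expect_equal(sum(cc$tp), attr(cc, "n_agree"))
  }
})

test_that("classification metrics follow the four confusion ratios", {
  cc <- data.frame(class = "sitting", tp = 8, fp = 5, tn = 5, fn = 2)
  m <- classification_metrics(cc)
  expect_equal(round(m$sensitivity, 3), 0.800)
  expect_equal(round(m$specificity, 3), 0.500)
  expect_equal(round(m$ppv, 3), 0.615)
  expect_equal(round(m$npv, 3), 0.714)

  perfect <- data.frame(class = "lying", tp = 10, fp = 0, tn = 20, fn = 0)
  expect_true(all(unlist(classification_metrics(perfect)[, -1]) == 1))

  none <- data.frame(class = "lying", tp = 0, fp = 0, tn = 5, fn = 5)
  m <- classification_metrics(none)
  expect_true(is.na(m$ppv))
  expect_true("lying:ppv" %in% attr(m, "undefined"))

  # scale invariance: multiplying all counts leaves the ratios unchanged
  cc2 <- cc; cc2[, -1] <- cc2[, -1] * 7
  expect_equal(classification_metrics(cc2)[, -1],
               classification_metrics(cc)[, -1])
})

test_that("ICC(2,1) matches a two-way ANOVA oracle and its edge cases", {
  m <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(icc_2_1(m), 1)

  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnorm(10, 50, 10), 5, 2)
    expect_equal(icc_2_1(m), icc21_aov(m), tolerance = 1e-10)
    expect_lte(icc_2_1(m), 1)
  }

  # absolute agreement penalises a constant offset that Pearson r ignores
  set.seed(32)
  r1 <- rnorm(10, 100, 5)
  m <- cbind(r1, r1 + 50)
  expect_lt(icc_2_1(m), stats::cor(m[, 1], m[, 2]) - 0.5)

  const <- matrix(5, 3, 2)
  expect_equal(as.numeric(icc_2_1(const)), 1)
  expect_true(attr(icc_2_1(const), "degenerate"))
  expect_error(icc_2_1(matrix(1:2, 1, 2)), "at least 2 subjects")
})

test_that("Bland-Altman bias and limits follow mean +/- 1.96 SD", {
  ba <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)

  ba <- bland_altman(c(15, 25, 35), c(10, 20, 30))
  expect_equal(ba$bias, 5)
  expect_equal(c(ba$loa_low, ba$loa_high), c(5, 5))

  set.seed(41)
  alg <- runif(50, 100, 200); ref <- alg + rnorm(50, 2, 4)
  ba <- bland_altman(alg, ref)
  d <- alg - ref
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(1234)
  alg <- rnorm(1000, 0, 1); ref <- rep(0, 1000)
  ba <- bland_altman(alg, ref)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gte(inside, 0.93)
})

test_that("duration errors implement AE and APE", {
  de <- duration_errors(100, 90)
  expect_equal(de$ae, 10)
  expect_equal(de$ape, 10)

  de <- duration_errors(c(60, 30), c(60, 30))
  expect_equal(de$ae, 0)
  expect_equal(de$ape, 0)

  de <- duration_errors(c(60, 30), c(66, 27))
  expect_equal(de$ae, 4.5)
  expect_equal(de$ape, 10)

  expect_error(duration_errors(c(60, 0), c(60, 10)), "positive")
  expect_error(duration_errors(c(60, 30), 60), "equal length")
})

test_that("bout matching pairs by greatest overlap within each label", {
  ref <- annotation_track(data.frame(
    start_s = c(0, 60, 120), end_s = c(60, 120, 180),
    label = c("sitting", "upright", "sitting")))
  pred <- annotation_track(data.frame(
    start_s = c(0, 55, 125), end_s = c(55, 125, 180),
    label = c("sitting", "upright", "sitting")))
  m <- match_bouts(pred, ref)
  expect_equal(nrow(m), 3)
  expect_equal(m$ref_start, c(0, 60, 120))
  expect_equal(m$alg_start, c(0, 55, 125))
  expect_equal(attr(m, "n_unmatched_ref"), 0)

  # an unmatched extra prediction is counted, not paired
  pred2 <- annotation_track(data.frame(
    start_s = c(0, 55, 125, 200), end_s = c(55, 125, 180, 220),
    label = c("sitting", "upright", "sitting", "lying")))
  m2 <- match_bouts(pred2, ref)
  expect_equal(nrow(m2), 3)
  expect_equal(attr(m2, "n_unmatched_pred"), 1)
})

test_that("evaluate_agreement bundles metrics, durations and errors", {
  sim <- simulate_recording(scripted_protocol(seed = 12))
  bouts <- classify_recording(sim$recording)
  report <- suppressWarnings(evaluate_agreement(bouts, sim$truth))
  expect_s3_class(report, "agreement_report")
  expect_gt(report$accuracy, 0.9)
  expect_equal(sort(report$metrics$class), sort(c("sitting", "lying", "upright")))
  expect_true(all(report$durations$reference_s > 0))
  expect_true(all(report$errors$n_matched >= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement_report(report, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("tp", "sensitivity", "ae_s") %in% names(tab)))
})
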