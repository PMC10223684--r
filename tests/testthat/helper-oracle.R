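# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorised code paths: explicit per-window loops and
# scans, coded straight from the classification algorithm's pseudocode.

# literal interpreter of the classification/detection phases: takes a
# window_features series, returns a data frame of labelled bouts
algorithm1_interpreter <- function(wfs, cfg = algo_config()) {
  nw <- nrow(wfs)
  arr <- integer(nw) # 1 indicates "upright"
  if (ceiling(mean(wfs$tilt_vt_filtered)) >= cfg$vt_upright_profile_deg &&
      ceiling(mean(wfs$tilt_ml_filtered)) >= cfg$ml_upright_profile_deg &&
      ceiling(mean(wfs$tilt_ap_filtered)) >= cfg$ap_upright_profile_deg) {
    m <- mean(wfs$std_sum_filtered)
    for (w in seq_len(nw)) {
      if (wfs$std_sum_filtered[w] >= m) {
        ok <- TRUE
        if (cfg$mode == "gated") {
          ok <- wfs$tilt_vt_filtered[w] >= cfg$vt_upright_window_deg &&
            wfs$tilt_ap_filtered[w] >= cfg$ap_upright_window_deg
        }
        if (ok) arr[w] <- 1L
      }
    }
  } else {
    for (w in seq_len(nw)) {
      if (wfs$tilt_vt_filtered[w] >= cfg$vt_upright_window_deg &&
          wfs$tilt_ap_filtered[w] >= cfg$ap_upright_window_deg) {
        arr[w] <- 1L
      }
    }
  }

  # find start_frame and end_frame of potential upright bouts by scanning,
  # the gaps between them being non-upright bouts
  segs <- list()
  w <- 1L
  while (w <= nw) {
    v <- arr[w]
    e <- w
    while (e < nw && arr[e + 1L] == v) e <- e + 1L
    segs[[length(segs) + 1L]] <- list(start = w, end = e, upright = v == 1L)
    w <- e + 1L
  }

  labels <- character(length(segs))
  preceding <- NA_real_
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    m_ap <- mean(wfs$tilt_ap_filtered[s$start:s$end])
    if (s$upright || is.na(preceding)) {
      if (m_ap < cfg$ap_lying_fixed_deg) {
        labels[i] <- "lying"
      } else if (m_ap < cfg$ap_sitting_fixed_deg) {
        labels[i] <- "sitting"
      } else {
        labels[i] <- "upright"
      }
    } else {
      if (m_ap < preceding / cfg$lying_ratio) {
        labels[i] <- "lying"
      } else if (m_ap < preceding) {
        labels[i] <- "sitting"
      } else {
        labels[i] <- "upright"
      }
    }
    if (labels[i] == "upright") preceding <- m_ap
  }

  out <- data.frame(
    start_frame = vapply(segs, function(s) s$start - 1L, 0L),
    end_frame = vapply(segs, function(s) s$end, 0L),
    label = labels
  )
  # merge neighbouring bouts that ended up with the same label
  merged <- out[1, , drop = FALSE]
  for (i in seq_len(nrow(out) - 1L) + 1L) {
    j <- nrow(merged)
    if (out$label[i] == merged$label[j]) {
      merged$end_frame[j] <- out$end_frame[i]
    } else {
      merged <- rbind(merged, out[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

# brute-force per-frame confusion counts: scan every frame, scan every
# interval
brute_confusion <- function(pred, ref, resolution) {
  p <- if (inherits(pred, "annotation_track")) pred$intervals else
    data.frame(start_s = pred$start_s, end_s = pred$end_s, label = pred$label)
  r <- if (inherits(ref, "annotation_track")) ref$intervals else
    data.frame(start_s = ref$start_s, end_s = ref$end_s, label = ref$label)
  lo <- max(min(p$start_s), min(r$start_s))
  hi <- min(max(p$end_s), max(r$end_s))
  nf <- floor((hi - lo) / resolution + 1e-9)
  lookup <- function(iv, t) {
    for (i in seq_len(nrow(iv))) {
      if (t >= iv$start_s[i] && t < iv$end_s[i]) return(iv$label[i])
    }
    NA_character_
  }
  counts <- matrix(0L, 3, 4,
                   dimnames = list(c("sitting", "lying", "upright"),
                                   c("tp", "fp", "tn", "fn")))
  for (k in seq_len(nf)) {
    t <- lo + (k - 1) * resolution
    lp <- lookup(p, t); lr <- lookup(r, t)
    if (is.na(lp) || is.na(lr)) next
    for (cl in rownames(counts)) {
      if (lp == cl && lr == cl) counts[cl, "tp"] <- counts[cl, "tp"] + 1L
      else if (lp == cl) counts[cl, "fp"] <- counts[cl, "fp"] + 1L
      else if (lr == cl) counts[cl, "fn"] <- counts[cl, "fn"] + 1L
      else counts[cl, "tn"] <- counts[cl, "tn"] + 1L
    }
  }
  counts
}

# ICC(2,1) via stats::aov mean squares
icc21_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  rn <- trimws(rownames(tab))
  msr <- tab[rn == "subj", "Mean Sq"]
  msc <- tab[rn == "rater", "Mean Sq"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
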