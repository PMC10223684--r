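#' Frame-level confusion counts
#'
#' Rasterises a predicted bout sequence and a reference annotation track onto
#' a common frame grid (0.01 s by default, matching a 100 Hz recording) over
#' the intersection of their spans, then counts one-vs-rest true/false
#' positives/negatives per class. A frame takes the label of the half-open
#' interval containing its start time; frames not covered by both tracks
#' (gaps) are dropped from the grid.
#'
#' @param pred Predicted [bout_sequence()] (or annotation track).
#' @param ref Reference [annotation_track()].
#' @param resolution Frame length in seconds (default 0.01).
#' @return An object of class `confusion_counts`: data frame with one row
#'   per class (`tp`, `fp`, `tn`, `fn`) and attributes `n_frames`,
#'   `n_agree`.
#' @export
frame_confusion <- function(pred, ref, resolution = 0.01) {
  p <- interval_df(pred)
  r <- interval_df(ref)
  lo <- max(min(p$start_s), min(r$start_s))
  hi <- min(max(p$end_s), max(r$end_s))
  if (hi - lo <= resolution / 2)
    stop("prediction and reference have no usable overlap", call. = FALSE)
  mismatch <- max(abs(min(p$start_s) - min(r$start_s)),
                  abs(max(p$end_s) - max(r$end_s)))
  if (mismatch > resolution)
    warning(sprintf("span mismatch of %.3f s; using the %.2f-%.2f s intersection",
                    mismatch, lo, hi))
  nf <- floor((hi - lo) / resolution + 1e-9)
  t <- lo + (seq_len(nf) - 1) * resolution
  lab_p <- labels_at(p, t)
  lab_r <- labels_at(r, t)
  keep <- !is.na(lab_p) & !is.na(lab_r)
  lab_p <- lab_p[keep]; lab_r <- lab_r[keep]
  n <- length(lab_p)
  if (n == 0L) stop("no frames covered by both tracks", call. = FALSE)
  out <- do.call(rbind, lapply(.sb_labels, function(cl) {
    tp <- sum(lab_p == cl & lab_r == cl)
    fp <- sum(lab_p == cl & lab_r != cl)
    fn <- sum(lab_p != cl & lab_r == cl)
    data.frame(class = cl, tp = tp, fp = fp, tn = n - tp - fp - fn, fn = fn)
  }))
  structure(out, class = c("confusion_counts", "data.frame"),
            n_frames = n, n_agree = sum(lab_p == lab_r),
            resolution = resolution)
}

# label of the half-open interval containing each time, NA outside coverage
labels_at <- function(iv, t) {
  idx <- findInterval(t, iv$start_s)
  lab <- rep(NA_character_, length(t))
  ok <- idx >= 1L
  inside <- ok & t < iv$end_s[pmax(idx, 1L)]
  lab[inside] <- iv$label[idx[inside]]
  lab
}

#' Sensitivity, specificity, PPV and NPV per class
#'
#' The four one-vs-rest ratios: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)`. A ratio with a zero denominator is
#' undefined and returned as `NA` with the affected cells listed in the
#' `undefined` attribute.
#'
#' @param cc A [frame_confusion()] result (or any data frame with columns
#'   `class`, `tp`, `fp`, `tn`, `fn`).
#' @return Data frame with columns `class`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (proportions in `[0, 1]`).
#' @export
classification_metrics <- function(cc) {
  cc <- as.data.frame(cc)
  stopifnot(all(c("class", "tp", "fp", "tn", "fn") %in% names(cc)))
  if (any(cc[c("tp", "fp", "tn", "fn")] < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    class = cc$class,
    sensitivity = ratio(cc$tp, cc$tp + cc$fn),
    specificity = ratio(cc$tn, cc$tn + cc$fp),
    ppv = ratio(cc$tp, cc$tp + cc$fp),
    npv = ratio(cc$tn, cc$tn + cc$fn)
  )
  undef <- which(is.na(as.matrix(out[, -1])), arr.ind = TRUE)
  attr(out, "undefined") <- if (nrow(undef))
    paste(out$class[undef[, 1]], colnames(out)[-1][undef[, 2]], sep = ":")
  else character(0)
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computes the single-measure absolute-agreement intraclass correlation from
#' the two-way ANOVA mean squares of an `n x k` matrix (subjects x raters):
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`, where `MSR`,
#' `MSC` and `MSE` are the row (subject), column (rater) and residual mean
#' squares.
#'
#' @param ratings Numeric matrix, `n >= 2` subjects by `k >= 2` raters,
#'   complete (no missing values).
#' @return ICC value in `(-Inf, 1]`. If all ratings are identical the
#'   decomposition is degenerate and 1 is returned with attribute
#'   `degenerate = TRUE`.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("ICC(2,1) needs at least 2 subjects and 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  grand <- mean(ratings)
  if (all(abs(ratings - grand) < 1e-12))
    return(structure(1, degenerate = TRUE))
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `algorithm - reference`; the bias is their mean
#' and the limits of agreement are `bias +/- 1.96 * SD` (sample SD, classical
#' formulation).
#'
#' @param algorithm,reference Paired numeric vectors (e.g. per-subject total
#'   durations, s), length >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, `n`, and the
#'   `differences` and `means` used (for plotting).
#' @export
bland_altman <- function(algorithm, reference) {
  stopifnot(length(algorithm) == length(reference), length(algorithm) >= 2L)
  d <- algorithm - reference
  s <- sd(d)
  bias <- mean(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd = s, n = length(d), differences = d,
         means = (algorithm + reference) / 2),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.3f, LoA = [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference (`algorithm - reference`) against pairwise mean, with the bias
#' and limits of agreement as horizontal lines.
#'
#' @param ba A [bland_altman()] result.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(ba, title = "Bland-Altman") {
  stopifnot(inherits(ba, "bland_altman"))
  df <- data.frame(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (s)",
                  y = "Algorithm - reference (s)", title = title) +
    ggplot2::theme_minimal()
}

#' Absolute and absolute-percentage duration errors
#'
#' For matched bout durations: `AE = mean(|R - A|)` seconds and
#' `APE = 100 * mean(|R - A| / R)` percent, where `R` are reference and `A`
#' algorithm durations.
#'
#' @param ref_durs,alg_durs Equal-length vectors of matched bout durations
#'   (s); reference durations must be positive.
#' @return List with `ae` (s), `ape` (%), `n`.
#' @export
duration_errors <- function(ref_durs, alg_durs) {
  if (length(ref_durs) != length(alg_durs))
    stop("ref_durs and alg_durs must have equal length", call. = FALSE)
  if (length(ref_durs) == 0L) stop("no matched bouts", call. = FALSE)
  if (any(ref_durs <= 0))
    stop("reference durations must be positive", call. = FALSE)
  list(ae = mean(abs(ref_durs - alg_durs)),
       ape = 100 * mean(abs(ref_durs - alg_durs) / ref_durs),
       n = length(ref_durs))
}

#' Match predicted bouts to reference bouts by temporal overlap
#'
#' Each reference bout is paired with the same-label predicted bout sharing
#' the greatest temporal overlap; every predicted bout is used at most once
#' (ties and competition resolved by descending overlap). Unmatched bouts on
#' either side are counted, not paired.
#'
#' @param pred Predicted [bout_sequence()] (or interval table).
#' @param ref Reference [annotation_track()] (or interval table).
#' @return Data frame of matched pairs (`label`, `ref_start`, `ref_end`,
#'   `alg_start`, `alg_end`, `ref_dur`, `alg_dur`, `overlap`) with
#'   attributes `n_unmatched_ref`, `n_unmatched_pred`.
#' @export
match_bouts <- function(pred, ref) {
  p <- interval_df(pred); r <- interval_df(ref)
  cand <- expand.grid(i = seq_len(nrow(r)), j = seq_len(nrow(p)))
  cand <- cand[r$label[cand$i] == p$label[cand$j], , drop = FALSE]
  if (nrow(cand)) {
    cand$overlap <- pmax(0, pmin(r$end_s[cand$i], p$end_s[cand$j]) -
                              pmax(r$start_s[cand$i], p$start_s[cand$j]))
    cand <- cand[cand$overlap > 0, , drop = FALSE]
    cand <- cand[order(-cand$overlap), , drop = FALSE]
  }
  used_i <- logical(nrow(r)); used_j <- logical(nrow(p))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      label = r$label[i],
      ref_start = r$start_s[i], ref_end = r$end_s[i],
      alg_start = p$start_s[j], alg_end = p$end_s[j],
      ref_dur = r$end_s[i] - r$start_s[i],
      alg_dur = p$end_s[j] - p$start_s[j],
      overlap = cand$overlap[k])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), ref_start = numeric(0),
               ref_end = numeric(0), alg_start = numeric(0),
               alg_end = numeric(0), ref_dur = numeric(0),
               alg_dur = numeric(0), overlap = numeric(0))
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            n_unmatched_ref = sum(!used_i),
            n_unmatched_pred = sum(!used_j))
}

#' Agreement report for one prediction/reference pair
#'
#' Bundles the frame-level confusion counts and derived metrics, per-class
#' total durations, and matched-bout duration errors (AE, APE) for a single
#' recording.
#'
#' @inheritParams frame_confusion
#' @return An object of class `agreement_report`: list with `confusion`,
#'   `metrics`, `accuracy` (overall frame agreement), `durations` (per-class
#'   totals for both tracks, s), `matches`, and per-class `errors`
#'   (AE s / APE %).
#' @export
evaluate_agreement <- function(pred, ref, resolution = 0.01) {
  cc <- frame_confusion(pred, ref, resolution)
  metrics <- classification_metrics(cc)
  p <- interval_df(pred); r <- interval_df(ref)
  durs <- do.call(rbind, lapply(.sb_labels, function(cl) data.frame(
    class = cl,
    algorithm_s = sum((p$end_s - p$start_s)[p$label == cl]),
    reference_s = sum((r$end_s - r$start_s)[r$label == cl])
  )))
  mb <- match_bouts(pred, ref)
  errors <- do.call(rbind, lapply(.sb_labels, function(cl) {
    m <- mb[mb$label == cl, , drop = FALSE]
    if (nrow(m) == 0L)
      return(data.frame(class = cl, ae_s = NA_real_, ape_pct = NA_real_,
                        n_matched = 0L))
    de <- duration_errors(m$ref_dur, m$alg_dur)
    data.frame(class = cl, ae_s = de$ae, ape_pct = de$ape, n_matched = de$n)
  }))
  structure(
    list(confusion = cc, metrics = metrics,
         accuracy = attr(cc, "n_agree") / attr(cc, "n_frames"),
         durations = durs, matches = mb, errors = errors,
         resolution = resolution),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> frame accuracy %.2f%% at %g s resolution\n",
              100 * x$accuracy, x$resolution))
  print(x$metrics, row.names = FALSE)
  cat("durations (s):\n"); print(x$durations, row.names = FALSE)
  cat("matched-bout errors:\n"); print(x$errors, row.names = FALSE)
  invisible(x)
}

#' Export an agreement report's metric table as CSV
#'
#' One row per class: confusion counts, the four classification metrics,
#' total durations and matched-bout errors.
#'
#' @param report An [evaluate_agreement()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  df <- merge(merge(as.data.frame(report$confusion), report$metrics,
                    by = "class"),
              merge(report$durations, report$errors, by = "class"),
              by = "class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
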