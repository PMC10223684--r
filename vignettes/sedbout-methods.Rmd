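---
title: "Detecting sitting, lying and upright bouts from a lower-back accelerometer"
author: "sedbout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sitting, lying and upright bouts from a lower-back accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedbout)
```

## The problem

Sedentary behaviour — waking time spent sitting, reclining or lying — is a
health risk factor in its own right, and distinguishing *posture* (sitting
vs lying vs upright) is exactly what activity-count accelerometry is worst
at. A single triaxial accelerometer worn on the lower back sees both the
gravity vector (which encodes trunk orientation) and movement intensity
(which separates walking from still postures). `sedbout` implements a
deterministic, threshold-based classifier over these two channels, a signal
simulator to exercise it, and the agreement statistics used to validate
posture classifiers against annotated reference recordings.

The device convention is `ax` vertical, `ay` mediolateral, `az`
anterior–posterior, in units of g. At rest the accelerometer reads +1 g
along whichever axis points upward, so the *tilt angle* of axis $x$ against
the total acceleration vector,

$$\theta_x = \arccos\!\left(\frac{x}{\sqrt{a_x^2+a_y^2+a_z^2}}\right)\cdot\frac{180}{\pi},$$

measures trunk orientation: a person standing bolt upright with the vertical
axis pointing down the spine shows $\theta_{VT} \approx 180°$ and
$\theta_{AP} \approx 90°$; lying supine swings the anterior–posterior axis
toward vertical and $\theta_{AP}$ collapses toward 0°.

## The classification pipeline

1. **Resampling.** Wearable real-time clocks drift; recordings are
   interpolated onto a uniform 100 Hz grid anchored at the first timestamp
   and clipped to the recorded span, using shape-preserving piecewise-cubic
   Hermite interpolation (Fritsch–Carlson `monoH.FC`; monotone between
   knots, no overshoot). No extrapolation is ever performed — cubic
   extrapolation beyond the knots is undefined behaviour.

2. **Filtering.** Each axis passes a 2nd-order low-pass Butterworth at
   17 Hz, applied forward and backward. The two-pass (zero-phase) scheme
   cancels the phase response — bout boundaries are not shifted in time —
   and squares the magnitude response. Edges are handled by even (mirror)
   extension of 3× the filter order, with each pass seeded at its DC steady
   state, so constant signals pass through bit-exactly.

3. **Windowing.** The signal is cut into non-overlapping 0.1 s windows
   (10 samples at 100 Hz; one feature value per 0.1 s; a trailing partial
   window is dropped). Per window the pipeline computes the per-axis
   standard deviations of the offset-removed filtered axes and their sum
   `std_sum` (movement intensity), and the three tilt angles from the
   window-mean filtered acceleration vector. Two separate signal paths are
   deliberate: offset removal (mean subtraction) is applied only on the
   SD path, because subtracting the mean destroys the gravity component
   that the arccos tilt formulas require — tilt thresholds like
   $\theta_{VT} \ge 150°$ are only meaningful on gravity-bearing signals.
   (The SD itself is invariant to the mean shift, so both paths share one
   filtered signal internally.) Using the window-*mean* vector for the
   arccos stabilises the angle when the instantaneous magnitude passes near
   zero; the difference against per-sample tilt is far below the smoothing
   filter's resolution. A window whose mean vector has zero magnitude
   (possible only in degenerate synthetic input) carries the previous
   window's angles, 90° for a first window.

4. **Secondary smoothing.** `std_sum` is low-passed at 1 Hz and the three
   tilt series at 0.25 Hz (both 2nd-order zero-phase), at the 10 Hz window
   rate — these are window-level series, so the window rate is the natural
   sampling rate for them. Filtered tilts are clipped to [0°, 180°]. A
   recording yielding too few windows to support the filter's edge padding
   (under ~0.7 s) passes the raw series through unfiltered rather than
   failing.

5. **Candidate profiling.** The wearer is profiled as *upright-likely*
   when `ceiling(mean)` of the filtered VT/ML/AP tilt series reaches
   150°/90°/90°. The ceiling is applied exactly as in the profiling rule
   (so a 149.2° mean passes the 150° test); the per-window tests below use
   plain comparisons.

6. **Upright-window detection.** For upright-likely wearers, a window is
   flagged as potential upright movement when its filtered `std_sum`
   reaches the whole-recording mean of that channel (the profiling quantity
   already computed — a running mean is not used). In the default
   `"gated"` mode the flag additionally requires the per-window tilt test
   $\theta_{VT} \ge 140°$ and $\theta_{AP} \ge 75°$, confirming upright
   posture; `"strict"` mode applies the movement test alone, which is the
   more literal reading of the detection rule but cannot distinguish
   vigorous non-upright movement (e.g. restless lying) from walking. Both
   are exposed via `algo_config(mode = )`. For non-upright-likely wearers
   the tilt test alone decides.

7. **Bout extraction and labelling.** Maximal runs of flagged windows
   become potential upright bouts; the gaps between them are non-upright
   segments. Potential upright bouts are relabelled by their mean filtered
   anterior–posterior tilt: < 40° → lying, < 80° → sitting, otherwise
   confirmed upright. Each non-upright segment is labelled *adaptively*
   against the preceding confirmed upright bout with mean tilt $\mu$:
   below $\mu/2.5$ → lying, below $\mu$ → sitting, otherwise upright. A
   segment with no preceding confirmed upright bout falls back to the fixed
   40°/80° thresholds (the adaptive rule is undefined there, and the fixed
   rule is the classifier's own fallback for candidate bouts). All
   comparators are implemented exactly as stated, with `<` at the labelling
   thresholds and `>=` at the detection thresholds; values exactly at a
   threshold therefore take the upper branch of `>=` tests and the upper
   label of `<` tests. Adjacent same-label bouts merge; postural
   transitions are absorbed into the enclosing bouts. No minimum bout
   duration is imposed by default (`min_bout_s = 0` exists for users who
   want one).

### Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `vt/ml/ap_upright_profile_deg` | 150 / 90 / 90 | deg | upright-likely profiling on mean filtered tilts |
| `vt_upright_window_deg`, `ap_upright_window_deg` | 140 / 75 | deg | per-window upright confirmation |
| `ap_lying_fixed_deg`, `ap_sitting_fixed_deg` | 40 / 80 | deg | fixed lying/sitting split of candidate bouts |
| `lying_ratio` | 2.5 | — | adaptive lying divisor vs preceding upright bout |
| `accel_cutoff_hz` | 17 | Hz | axis low-pass |
| `std_cutoff_hz`, `tilt_cutoff_hz` | 1 / 0.25 | Hz | window-series smoothing |
| `window_s` | 0.1 | s | feature window |
| `target_rate_hz` | 100 | Hz | uniform grid |
| `mode` | gated | — | upright-likely branch behaviour |

The angle thresholds are the algorithm's published operating point; they are
exposed because the sitting/lying boundary in particular (40°/80°) is
population-dependent (estimated on older adults wearing the device at L5).

## The simulator

`simulation_script()` renders an activity script as a triaxial recording
plus ground truth. Each posture contributes its unit gravity vector in
device axes plus Gaussian noise; walking adds a 2 Hz sinusoidal gait
component (0.15 g vertical, 40% of that in quadrature on the
anterior–posterior axis) and broadband noise (0.08 g per axis) so that
windowed SD separates walking from still postures by better than a factor
of five. Orientations are slerp-interpolated over 2 s windows centred on
segment boundaries (a typical sit-to-stand time in adults over 75);
timestamps carry 1 ms Gaussian jitter to emulate clock drift;
synchronisation taps are 0.05 s triphasic spikes of ±4 g.

Default orientations (device on the lower back): standing $(-1, 0, 0)$
($\theta_{VT}=180°$), walking with ~5° forward trunk lean
($\theta_{AP}\approx 85°$), sitting $(-0.707, 0, 0.707)$
($\theta_{AP}=45°$, reclined trunk/posterior pelvic tilt), lying supine
$(-0.342, 0, 0.940)$ ($\theta_{AP}\approx 20°$, anterior axis pointing
up). True per-posture tilt distributions for any given cohort are not
published, so these are explicit assumptions — chosen to be physically
plausible *and* separable by the classifier's thresholds, which is asserted
at script construction (a script violating separability is refused rather
than silently producing an untestable fixture). All are overridable, per
script and per segment.

`scripted_protocol()` encodes the in-home validation sequence: lounge sit
60 s, walk, dining sit 60 s, walk, supine lie 60 s, bed-edge sit 3 s, stand
60 s, three walks, lounge sit 60 s, quiet stand 60 s, with three 1 s-spaced
taps at each end during 5 s standing lead-in/lead-out. Walk durations are
prescribed only as "comfortable pace"; the script uses 15 s for direct
walks and 20 s for the two turn-back walks.

**What the simulator does not emulate:** realistic gait kinematics,
soft-tissue artefact, device micro-rotations within a posture, gyroscope
channels, and the within-posture tilt variability of real wearers. Passing
the simulation-recovery checks therefore demonstrates that the pipeline
implements its rules correctly and recovers bouts under plausible signal
conditions — it does *not* re-establish the classifier's published
agreement with video annotation of real participants, which requires the
original recordings.

## Validation statistics

* **Frame-level confusion** at 0.01 s resolution (matching 100 Hz): both
  label tracks are rasterised over the intersection of their spans; a frame
  takes the label of the half-open interval containing its start time, so
  no frame is double-counted at bout boundaries. One-vs-rest TP/FP/TN/FN
  per class feed sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$,
  PPV $TP/(TP+FP)$ and NPV $TN/(TN+FN)$; zero-denominator ratios are
  reported as undefined rather than coerced to 0 or 1. Frames are pooled
  across a recording (and across recordings in the acceptance pipeline);
  per-recording values are available from per-recording reports.

* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measure — from the two-way ANOVA mean squares:
  $\mathrm{ICC} = (MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$.
  An all-identical matrix has no defined variance decomposition and returns
  1 with a degeneracy flag.

* **Bland–Altman**: differences are fixed as algorithm − reference; limits
  of agreement are bias ± 1.96·SD (sample SD, classical formulation — not a
  t-quantile).

* **AE / APE**: mean absolute (percentage) error over *matched* bout
  durations. Predicted bouts are paired to reference bouts of the same
  label by greatest temporal overlap, each used at most once; unmatched
  bouts are counted and excluded. Overlap matching is the standard
  convention and reduces to the identity pairing when bouts align.

## Problem sizes and numerical choices

The packaged validation pipeline (`scripts/acceptance.R`) simulates 10
scripted-protocol participants (~458 s each at 100 Hz, ≈ 460 000 frames
pooled), classifies them with default configuration, and recomputes every
statistic above from scratch. Per-participant segment durations vary ±20%
around the script — the protocol prescribes durations only approximately,
and without between-subject variance in the true durations ICC(2,1) is
undefined by construction. Test-suite checks use 2-minute random scripts
(20 seeds) for rule-interpreter equivalence and small closed-form fixtures
elsewhere.

Numerical points worth knowing:

* MATLAB fractional-day timestamps at datenum magnitudes (~7.3×10⁵ days)
  cannot represent a 0.01 s grid to better than ~2×10⁻⁵ s in double
  precision; conversion is exact only relative to the first sample of
  small-magnitude stamps. This is a representation limit of the export
  format, not of the reader.
* Tap detection is defined operationally (the inter-device synchronisation
  procedure is a physical action, not an algorithm): local maxima of the
  0.1 s-window summed SD above 8× its median (floored at 10⁻⁴ g), chained
  by expected spacing ± tolerance. The threshold multiple is exposed in the
  function signature because it is this package's own construction.
* The resampling grid never extrapolates; the last grid point is clamped to
  the final knot to avoid floating-point spill.
* Determinism: classification is purely deterministic; simulation restores
  the caller's RNG state and is bit-reproducible for a fixed script and
  seed.

## Known limitations

* The movement-intensity branch (upright-likely wearers in `strict` mode)
  carries no postural information: still standing falls below the mean
  `std_sum` and is missed, and vigorous non-upright movement is flagged.
  The `gated` default mitigates the second failure but not the first.
* The adaptive sitting/lying rule depends on the *preceding* upright bout;
  a recording that begins with a long sedentary stretch is labelled by the
  fixed thresholds until the first upright bout occurs.
* Short postural transitions are absorbed into neighbouring bouts by
  design; transition-level timing (sit-to-stand duration etc.) is out of
  scope.
* Thresholds were estimated for lower-back wear in older adults; other
  wear sites or populations will need a different operating point via
  `algo_config()`.
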