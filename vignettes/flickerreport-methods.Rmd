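---
title: "Phase flickering, alert calibration and report generation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase flickering, alert calibration and report generation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerreport)
```

## The problem

Frame-wise phase recognition of laparoscopic cholecystectomy video assigns
one of eight phases (P0 transition start, P1 preparation, P2 clipping,
P3 dissection, P4 hemostasis I, P5 gallbladder retrieval, P6 hemostasis II,
P7 transition end) to every frame, typically at 2 frames per second. Two
things can be done with such an annotation beyond archiving it. First, the
phase durations support a computer-aided operative note: standard text per
phase, with an alert wherever a duration deviates from a reference cohort.
Second, the annotation's *failure modes* are themselves informative:
clusters of rapidly changing, illogically ordered labels ("phase
flickering") concentrate around adverse events such as bleeding or a
difficult gallbladder retrieval, because the recognizer is fed images it
was not trained to expect. This package implements both uses: flicker
detection and profiling, cutoff calibration, duration alerts, annotator
concordance, and report rendering, plus a synthetic cohort simulator so
that every stage is testable without clinical recordings.

## The sliding-buffer classifier

A buffer of `buffer_width` frames (default 6) slides along the label
sequence with stride 1. Each window is classified into exactly one of
three states:

* **UNIFORM** — a single distinct label; no phase variation.
* **TRANSITION** — exactly two distinct labels, with every copy of the
  smaller label preceding every copy of the larger; the signature of a
  regular phase change.
* **FLICKER** — everything else.

Two conventions deserve note, because the trichotomy must be total and the
verbal rules alone are not:

* The two labels of a TRANSITION need not be numerically adjacent phases
  (1→3 is a legal transition: phases can be skipped); but a *descending*
  two-label window is FLICKER, since a backward phase jump is illogical.
* A window with exactly two interleaved labels (1,2,1,2,…) and a sorted
  window with three or more distinct labels are both FLICKER: neither is a
  clean two-phase change. This keeps TRANSITION a strict reading of
  "two labels in ascending block order" and routes all disorder to
  FLICKER.

The implementation classifies all windows at once from the vector of
adjacent label differences (a window is UNIFORM iff all its differences
are zero, a TRANSITION iff they are all non-negative with exactly one
positive); the test suite checks it exhaustively against a literal
restatement of the three rules over every width-6 window on three labels.

## FT groups

Frames are *active* when covered by at least one non-uniform window (the
window at start `s` covers frames `s … s + width − 1`). Attributing
window states to frames this way — any covering window counts — is a
deliberate, conservative choice: it makes "concerned frames" well defined
and is a superset of any narrower attribution.

Maximal runs of active frames are merged into **FT groups** when separated
by at most `round(merge_gap_seconds × fps)` inactive frames (default 10 s,
i.e. 20 frames at 2 fps); the comparison is inclusive, reading "an
interval of maximum 10 s" as merge-if-at-most. A group spans its first
through last active frame, and `contains_flicker` is a property of the
*merged* group: one flicker window anywhere in its span marks all its
frames as flicker-affected. A clean ordered course therefore yields
exactly 7 groups — one per phase boundary, each 2 × width − 2 = 10 frames
— and zero flicker frames, which is the baseline the profiling statistics
are read against.

Sequences shorter than the buffer are an error rather than an empty
profile: a degenerate input should fail loudly.

The per-surgery **flicker profile** reports the group count
(`n_ft_groups`), the total frames inside groups (`n_ft_frames`), and the
frames inside flicker-containing groups (`n_flicker_frames`). The
distinction matters because a long surgery has more transitions than a
short one but the same 7-group baseline, while flicker frames are pure
pathology; both counts are exposed and either can be used as the ROC
score.

## Cutoff calibration

Given profiles and per-surgery ground truth (regular vs. aberrant course),
`roc_calibrate()` runs an ROC analysis with higher scores predicting
aberrance. Curve construction and AUC use the standard pROC machinery
(fixed direction, candidate thresholds at midpoints between consecutive
distinct scores with infinite sentinels), so the AUC equals the pairwise
Mann–Whitney probability with ties counted half.

The operating cutoff maximizes **Youden's J** (sensitivity + specificity −
1) and is reported as the midpoint between the two adjacent observed
scores — on integer counts this yields half-integer cutoffs such as 11.5,
which cleanly separate counts ≤ 11 from ≥ 12. Ties in J break toward
higher specificity (then toward the higher threshold), favoring an alert
that rarely cries wolf: in this application a false alarm costs surgeon
attention on every regular case. When no midpoint improves on J = 0 the
flag-nothing classifier wins and the maximum observed score is returned,
which classifies identically under the strict `>` rule.

The alert defaults (11.5 FT groups, 212 FT frames) are reference values
for 2 fps cholecystectomy annotations; any new cohort with ground truth
should be recalibrated.

## Duration alerts

Per-phase duration is the *total* frame count with that label divided by
fps — robust to non-contiguous, flickered annotations — rather than a
boundary-to-boundary extent; the two coincide on clean annotations and
the frame-count reading requires no boundary estimation on disordered
ones. Durations always sum exactly to the sequence duration.

The reference band per phase is the 25th–75th percentile across the
cohort, computed with the linear-interpolation quantile (type 7, R's
default, matching the surrounding statistical toolchain). The alert rule
is strict: a duration below Q25 is `ALERT_SHORT`, above Q75 `ALERT_LONG`,
and a value exactly on either quartile is within the band. The three
statuses partition the positive line for any reference statistics.

## Concordance

Annotator agreement (e.g. network vs. expert) is frame-level accuracy
with a Clopper–Pearson exact 95% binomial interval, plus the 8×8
confusion matrix with ground truth in columns and prediction in rows, and
per-phase accuracy as column-wise recall. The exact interval was chosen
over a normal approximation because frame counts per surgery are large
but per-phase counts can be tiny, and exactness costs nothing. Pooling
across surgeries sums confusion counts before computing accuracy, i.e.
frame-weighted pooling. Sequences of unequal length or frame rate are
rejected, not truncated: silent alignment would fabricate agreement.

## Report generation

`build_report()` is a batch model of the surgeon interaction: each phase
section is GREEN (standard snippet verbatim) or RED (duration alert), a
RED section carries the surgeon's comment when supplied and otherwise the
standard snippet flagged as requiring an edit, and a raised flicker alert
adds a header prompt that likewise requires a comment. Completeness is
*computed*, never assumed: a document is complete only when every RED
section and any raised header alert carry non-empty surgeon text. An
uncommented RED section still renders — the standard text is not
forbidden, merely flagged — so a draft note is always available.

Rendering is referentially transparent (same document and style, same
bytes) in two styles: narrative prose paragraphs in phase order, or a
synoptic labeled field list. The shipped English snippets are generic
placeholders; institutions are expected to replace them via
`report_template()` or a template JSON.

## The synthetic cohort

`generate_cohort()` emulates what the pipeline needs from real data and
nothing more:

* Per-phase durations are log-normal with per-phase median seconds
  (defaults 45, 420, 150, 900, 180, 240, 150, 60 — plausible elective
  cholecystectomy scales, chosen once for illustration) and dispersion
  `sdlog = 0.35`, floored at 20 s by bounded resampling. The floor keeps
  every phase run long enough that transition activity never merges
  across neighboring boundaries at the default detector settings.
* Regular courses run P0…P7 in order with single-frame boundaries.
* Aberrant courses (default fraction 0.4, mirroring a 15-surgery cohort
  with 6 divergent) have their longest phase prolonged by a multiplier
  (default 2) and carry 3–7 flicker bursts — contiguous frames relabeled
  uniformly to wrong phases — placed inside that phase with margins and
  spacing exceeding the merge gap plus the buffer halo, so each burst
  forms its own FT group. Bursts relabel existing frames rather than
  inserting new ones, keeping the duration signal and the flicker signal
  independently controllable.
* One RNG stream per cohort, seeded from the config: cohorts are
  reproducible bit for bit.

What the simulator deliberately does *not* model: realistic confusion
structure between specific phase pairs, gradual boundary ambiguity,
phase order deviations, or any coupling between burst content and a
complication type. Passing tests on synthetic cohorts therefore
demonstrate that the algorithms implement their definitions and that the
pipeline separates engineered aberrance — not that the reference cutoffs
or accuracies transfer to any clinical dataset.

## Problem sizes and numerical choices

The test suite exercises: the window classifier exhaustively over all 729
width-6 windows on three labels; 100 seeded regular courses for the
7-group baseline; 1,000 random small ROC instances (n ≤ 20, with ties)
against pairwise enumeration; and a 60-surgery half-aberrant cohort with
a fixed 5-burst model for end-to-end separation. These sizes were chosen
as the smallest that make the properties non-trivial; all are seeded.

Remaining conventions: frame indexing is 1-based inclusive in the R
interfaces (the CSV interchange format is 0-based, converted at the
boundary); all second-valued thresholds are converted to frames by
rounding; the merge-gap comparison is inclusive; alert comparisons are
strict. Each of these is asserted by a boundary test.

## Known limitations

* The flicker statistic flags *that* a course is aberrant, not *what*
  happened; classifying flicker patterns into complication types would
  need far larger cohorts.
* Reference durations are unadjusted for patient or procedure covariates.
* The reference cutoffs (11.5 groups / 212 frames) are tied to 2 fps and
  a 6-frame buffer; recalibrate after changing either.
* Concordance requires frame-aligned annotations; resampling between
  differing frame rates is out of scope.
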