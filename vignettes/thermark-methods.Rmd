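---
title: "Detecting and classifying rodent scent marks in thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying rodent scent marks in thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thermark)
```

## The problem

Mice deposit urine and feces during social behavior experiments, and both
carry chemosensory information (identity, sex, rank, state). An overhead
long-wave infrared camera sees each fresh deposit as a warm blob — emitted
at body temperature on a cooler arena floor — that cools over tens of
seconds (feces and small urine) to a few minutes (large urine), ending as a
spot slightly *darker* than the dry floor. `thermark` turns radiometric
thermal video of such sessions into a table of time-stamped, localized,
classified deposition events, and summarises their dynamics.

The pipeline has four stages:

1. **Calibration** (`compute_nuc_image()`, `apply_calibration()`): a
   zero-mean fixed-pattern non-uniformity image (averaged frames of a
   uniform surface) is subtracted from every frame, then the offset between
   the in-view blackbody's mean apparent temperature and its setpoint
   (37 °C) is removed per frame, cancelling slow sensor drift.
2. **Preliminary detection** (`run_preliminary_detection()`): a heuristic
   hot-blob detector proposes candidate deposits.
3. **Classification** (`train_classifier()`, `classify_detections()`): a
   trainable patch-sequence classifier labels each candidate *urine*,
   *feces*, or *background*.
4. **Evaluation and dynamics** (`evaluate_detections()`,
   `deposition_events()`, `stage_summary()`): tolerance-based accuracy
   against manual tags, and per-minute/per-window deposition summaries.

A session has two stages — a habituation period in an empty arena and a
trial period with stimuli — separated by a short gap (stimulus
introduction, excluded from analysis). The two stages are processed
independently because the arena can shift slightly between them.

## The hot-blob detector

For frame $F_i$ the detector maintains a background $B_i$ built from
*mouse-inpainted* frames $N_j$: the mouse mask $M_i$ is the 8-connected
component of the dilated, thresholded difference $F_i - B_{i-1} > 1$ °C
(disk radius 2) that overlaps the arena floor the most, and
$N_i = N_{i-1}$ on $M_i$, $F_i$ elsewhere — each pixel keeps its last
mouse-free value. $B_i$ is the per-pixel minimum of the inpainted frames
4–5 s in the past (lags 36..44 frames at 8.66 fps); the initial background
is the per-pixel minimum of the first 20 s, relying on the mouse being
warmer than the floor and moving during that window.

The difference image is $D_i = F_i - \max(T, B_i)$, where $T$ is the
(lower) median of $B_i$ over mouse-free floor pixels; the floor median
keeps the sensitivity uniform over darker, urine-soaked floor regions. The
cooldown image is $CD_i = F_i - \min_{j \in [i, i+40\,\mathrm{s}]} F_j$. A
pixel is a candidate when

$$ D_i > \Delta T \;\wedge\; \lnot M_i \wedge \lnot M_{i-1} \;\wedge\;
   CD_i > 1.1\,°C \;\wedge\; CD_i > 0.5\, D_i $$

with $\Delta T = 1.6$ °C by default (detection counts are stable over
1.1–3 °C, which the test suite checks as a monotonicity property). The
mask is closed with an exact Euclidean disk of radius 4 (merging nearby
urine drops), 8-connected components are filtered (any pixel off the
floor, 8-adjacency to the current or previous mouse mask, size outside
2..900 px), and surviving blobs are associated over time: a blob
intersecting a track seen within the last 30 s merges into it (oldest
track on ties). Tracks detected in ≥ 2 frames become detections; the
selected frame maximizes blob peak intensity (earliest on ties) and the
representative pixel is that frame's peak pixel (row-major on ties). The
previous mouse mask is excluded alongside the current one because the
sensor's response time leaves recently vacated pixels slightly warm.

Numerical conventions, stated once and tested everywhere: coordinates are
0-based (x = column, y = row, origin top-left); frame intervals are closed;
second-based windows convert to frames so that the background lags are
exactly 36..44 frames at the nominal 8.66 fps; all threshold inequalities
are strict; the lower median is used for even counts; structuring elements
are exact Euclidean disks $\{\|p\| \le r\}$ and connectivity is always
8-way — these choices make the pipeline deterministic across platforms,
and the test suite holds the compiled production loop *bitwise* equal to a
naive per-frame reference implementation on random videos.

## The patch-sequence classifier

Each detection is represented by 78 grayscale patches of 65×65 px centered
on its representative pixel, taken at frames $i + 8k$, $k \in [-12..65]$ —
about $[-11\,\mathrm{s}, +60\,\mathrm{s}]$ around the selected frame. The
window reaches backwards because the mouse often occludes the deposit at
first, and forwards far enough to capture the full cooldown and any
displacement of feces. Temperatures map linearly to gray (10 °C → 0,
40 °C → 255, clipped); frames outside the video, and pixels outside the
frame, are padded with a uniform 22 °C patch (gray 102). Consecutive
patch triples form the three channels of one token image (26 tokens,
temporal channel order).

The full-scale architecture this mirrors is a detection-transformer-style
classifier: a 50-layer residual backbone (dilated final stage) over each
RGB-packed triple, a position-time encoding — the sinusoidal encoding of
$x$, $y$ and $t$ (the time axis encoded with the same functional form as a
spatial axis, 128 dims each) concatenated and mapped by one trainable
affine layer to 256 — an encoder-decoder with a **single query**, and a
classification head (no bounding boxes). That configuration is recorded in
`classifier_config(backbone = "reference")` for documentation. The
trainable implementation shipped here is the desk-scale `tiny` backbone:
each token is embedded from an average-pooled 13×13 view of its triple
plus a full-resolution 13×13 central crop (small feces span only a few
pixels and would vanish under pooling alone), the position-time encoding
is added through a trainable projection, a single trainable query computes
softmax attention over the 26 token states, and a linear head maps the
attention-pooled state to the three class scores. Everything is explicit
matrix algebra with hand-derived gradients (verified against finite
differences in the test suite), trained full-batch with Adam and a short
learning-rate warmup.

Training data per session: positives at every manual tag; 40 random
background negatives (20 per stage) resampled while closer than 25 px and
within $[-10, +30]$ s of any tag; hard negatives from preliminary
detections matching no tag. Augmentation (one draw per example): positives
get a time shift from $[-3, +6]$ s (absorbing tag-vs-detection timing
offsets); all examples get a ±2 px spatial shift, optional flips and a
rotation from {0°, 90°, 180°, 270°}. Positives receive two extra augmented
copies by default because the 40 random negatives per session would
otherwise outnumber them four to one.

The default tiny schedule is 120 epochs at learning rate $10^{-3}$ with a
factor-10 drop after epoch 100; `reference_training_schedule()` records
the full-scale two-round recipe (230 epochs then 50 warm-started epochs,
backbone at $10^{-5}$, rest at $10^{-4}$, late factor-10 drops).

## Accuracy evaluation

A manual tag is correctly detected when a same-label detection lies within
20 px and 15 s (inclusive); all same-label detections in that window are
absorbed, not false alarms (large or smeared urine is often tagged as
several events that the detector unifies). If only wrong-label detections
are in the window, the closest (spatial distance, then |Δt|, then lowest
id) is that event's misclassification. Events are processed greedily in
order of occurrence; a claimed detection is unavailable to later events,
and detections never claimed by any event are false alarms. The confusion
matrix has predicted rows {urine, feces, background, miss} × ground-truth
columns {urine, feces, background}: the miss row counts events the
preliminary detector never reached; the background column counts false
alarms by predicted label. Per class, precision = TP/(TP+FP), recall =
TP/(TP+FN) (zero denominators give 0), F1 is their harmonic mean, and the
mean F1 is the plain average of the urine and feces F1. Stratified reports
(stage windows, floor thirds along the arena's long axis, or any custom
strata) leave a class `NA` where it has no ground truth — F1 is undefined
there, not zero.

## The session simulator

`render_session()` is the test substrate for everything above. It renders:
a static floor field (mean 25 °C with smooth spatial texture), a
soft-edged mouse disk (35 °C) following a reflecting random walk with
optional dwells, scheduled deposits that rise by `peak_dT` and decay as

$$ T(t) = T_{floor} + (\Delta T_{peak} + d)\, e^{-(t-t_0)/\tau} - d $$

toward a dark offset $d$ (0.5 °C) *below* the floor — the warm-then-dark
signature of real deposits — plus Gaussian sensor noise, a fixed
zero-mean non-uniformity pattern, global sinusoidal drift, and a 37 °C
blackbody patch. The emitted calibration bundle inverts the sensor model
up to noise, and ground truth and annotation come straight from the
schedule, so every downstream claim can be checked against exact truth.
A fixed seed reproduces a session byte for byte.

Two modelling notes. First, with a single-exponential cooldown the
fractional test $CD > 0.5\,D$ is only satisfiable when
$\tau < 40/\ln 2 \approx 57.7$ s, so the preset time constants stay at or
below 52 s; real large urine cools multi-exponentially (fast initial loss,
slow tail), which is why the detector caps the fractional requirement at
one half in the first place. Second, the simulated mouse (radius 12 px at
the preset scale) must overlap more floor than any fresh urine blob:
the mouse-mask rule picks the component with maximal floor overlap, and a
mouse smaller than a urine spot makes the detector track the *mouse* as a
giant smeared deposit — a real failure mode of the heuristic that the
simulator's proportions respect.

Shipped presets (`sim_preset()`): `easy` — 160×120 px, two 2-minute
stages, 5 urine (radius 5–8 px, τ 40–52 s) + 5 feces (radius 1.5–2.5 px,
τ 30–45 s) per session, noise σ = 0.05 °C, the mouse kept ≥ 25 px from
deposit sites around deposition times; `occlusion` — the mouse dwells on
and near deposit sites; `dense` — 10 + 10 events per session. The preset
frame is a scaled-down arena (pixel area is left at the nominal
0.02 cm²); event separation (≥ 25 px within a stage) keeps blobs from
merging under the radius-4 closing and keeps tags unambiguous under the
20 px matching tolerance.

What the simulator deliberately does not model — and what passing tests on
it therefore cannot show about real data: fur and posture (the mouse is a
soft disk), urine smearing by locomotion, feces displaced while warm (the
published failure mode that produces background-as-feces errors),
multi-animal arenas, reflections from walls, and physically accurate
radiometry. Synthetic results demonstrate that the implementation behaves as
documented, not that comparable accuracy holds on any particular
laboratory's real videos.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use desk-scale problem sizes,
chosen as the package's verification conditions: bitwise detector
equivalence on twenty random 24×24×300 videos; detection recall on ten
`easy` sessions (localization ≤ 3 px, timing ≤ 15 s); an end-to-end run
that trains the tiny classifier on twenty simulated sessions and scores
five held-out sessions with the matcher (mean F1 ≥ 0.8); matcher equality
with a brute-force reference on 200 random configurations; threshold
monotonicity over ΔT ∈ {1.1, 1.6, 2.0, 3.0}; and byte-determinism of
every CLI subcommand under a fixed seed. All randomness flows from
explicit integer seeds.

## Known limitations

* The trainable classifier is the tiny configuration; the full-scale
  residual/transformer configuration is documented but not implemented
  here, and published trained weights are not reproduced.
* Deposits occluded by the mouse for long periods are missed by design
  (the preliminary detector needs the warm phase to be visible), and
  displaced feces are not tracked.
* The matcher's greedy order (events by time of occurrence) is a
  documented choice; the underlying matching principles do not define
  which of two simultaneous events claims a shared detection.
* Rates in `stage_summary()` use the canonical windows of 15-minute
  habituations and 5-minute trials; shorter simulated stages truncate the
  windows and the truncated duration is used as the denominator.
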