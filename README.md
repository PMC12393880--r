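# thermark

Automatic detection and classification of mouse urine and fecal
depositions from overhead radiometric thermal video.

Scent marking — urination and defecation during behavioral experiments —
carries social information (identity, sex, rank, internal state), but
classical urine mapping (the void spot assay) has no temporal resolution
and is distorted by smearing. In thermal video every fresh deposit appears
as a warm blob at body temperature on a cooler arena floor and then cools
to a spot slightly darker than the dry floor. `thermark` exploits that
warm-then-dark signature to produce a table of time-stamped, localized,
classified deposition events for each session, plus accuracy reports
against manual tags and deposition-dynamics summaries.

The pipeline:

1. **Radiometric calibration** — subtract a zero-mean fixed-pattern
   non-uniformity image, then the per-frame offset between an in-view
   blackbody's apparent temperature and its 37 °C setpoint.
2. **Preliminary hot-blob detection** — a heuristic detector: background
   `B_i` is the per-pixel minimum of mouse-inpainted frames 4–5 s in the
   past; candidates satisfy `D_i > 1.6 °C` (difference against
   `max(B_i, floor median)`), lie outside the current and previous mouse
   masks, and cool down by more than 1.1 °C *and* more than half their
   rise within the following 40 s. Blobs are closed (disk r = 4), filtered
   (on-floor, not touching the mouse, 2–900 px), and associated over time
   (30 s gap); tracks seen in ≥ 2 frames become detections.
3. **Patch-sequence classification** — 78 patches of 65×65 px at frames
   `i + 8k`, `k ∈ [-12..65]` (about −11 s to +60 s), gray-mapped
   (10 °C → 0, 40 °C → 255), packed as 26 three-channel tokens, with a
   sinusoidal (x, y, t) position-time encoding; a single-query attention
   classifier scores each detection as urine, feces or background.
4. **Evaluation & dynamics** — tolerance-based matching (≤ 20 px, ≤ 15 s,
   inclusive; same-label duplicates absorbed; closest-wrong-label counts
   as the misclassification), confusion matrix with miss row and
   background column, per-class precision/recall/F1 and mean F1; per-minute
   rates/areas, stage-window summaries, arena-side attribution.

A synthetic-session simulator (`render_session()`, presets `easy`,
`occlusion`, `dense`) renders full thermal sessions — moving mouse,
scheduled deposits with exponential cooldown to a below-floor dark offset,
sensor noise, fixed-pattern non-uniformity, drift, blackbody — with exact
ground truth, and is the substrate for the package's tests.

## Worked example

```r
library(thermark)

# simulate a session (160x120 px, two 2-min stages, 5 urine + 5 feces)
sim   <- render_session(sim_preset("easy", seed = 42))
video <- apply_calibration(sim$video, sim$calibration)

det <- run_preliminary_detection(video, sim$annotation)
det
#> # A tibble: 10 × 11
#>    det_id stage       selected_frame time_s     x     y area_px area_cm2 ...
#>     <int> <chr>                <int>  <dbl> <int> <int>   <int>    <dbl>
#>  1      1 habituation            109  12.6     54    42      38     0.76
#>  2      2 habituation            145  16.7     61    79     206     4.12
#>  ⋮
```

Ten preliminary detections for ten scheduled events; `x`, `y` is the
peak-intensity pixel of each blob (within 3 px of the simulated deposit
centers), `time_s` the selected-frame time, and `area_cm2` the union-mask
area at 0.02 cm²/px — so detection 2 is a ~4 cm² urine spot deposited
16.7 s into habituation.

Train a classifier on simulated sessions and score held-out ones:

```r
sessions <- lapply(1:6, function(s) {
  sim <- render_session(sim_preset("easy", seed = 200 + s))
  v   <- apply_calibration(sim$video, sim$calibration)
  list(video = v, annotation = sim$annotation,
       ground_truth = sim$ground_truth,
       detections = run_preliminary_detection(v, sim$annotation),
       id = as.character(s))
})
names(sessions) <- as.character(1:6)

manifest <- build_training_set(sessions, seed = 11)
examples <- collect_training_examples(sessions, manifest, seed = 12)
model    <- train_classifier(examples, seed = 13, dim_hw = c(120, 160))

held <- sessions[[6]]
classified <- classify_detections(model, held$video, held$detections)
report <- evaluate_detections(held$ground_truth, classified, fps = 8.66)
report
#> # A tibble: 2 × 7
#>   class    tp    fp    fn precision recall    f1
#> 1 urine     5     0     0         1      1     1
#> 2 feces     5     0     0         1      1     1
#> mean F1: 1.000
```

All ten held-out events detected and correctly classified. Dynamics:

```r
events <- deposition_events(classified, held$annotation, fps = 8.66)
per_minute_series(events, c(habituation = 120, trial = 120))
stage_summary(events, c(habituation = 120, trial = 120))
side_attribution(events, held$annotation)
```

`autoplot()` methods exist for thermal frames, confusion matrices,
accuracy reports and training histories; `tidy()`/`glance()` follow the
usual broom conventions.

## Command line

```sh
exec/thermark simulate --preset easy --seed 7 --out sess7
exec/thermark detect   --session sess7 --out det7.csv
exec/thermark train    --sessions sess7 --out model7
exec/thermark classify --session sess7 --detections det7.csv --model model7 --out cls7.csv
exec/thermark evaluate --ground-truth sess7/ground_truth.csv --detections cls7.csv --out report7.json
exec/thermark summarize --session sess7 --detections cls7.csv --out summ7
```

Every subcommand writes a JSON run manifest next to its output and is
byte-deterministic for a fixed seed.

## File formats

* Thermal container: multi-frame 16-bit TIFF + `.meta.json` sidecar
  (`T = raw * scale + offset`, default 0.01 °C quantization).
* Calibration bundle: NUC TIFF + blackbody-mask PNG + JSON.
* Annotation: JSON (floor/blackbody polygons, stage intervals, side map).
* Ground truth / detections / summaries: plain CSV.

See the methods vignette (`vignettes/thermark-methods.Rmd`) for the model
details, parameter meanings, simulator assumptions and known limitations.
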