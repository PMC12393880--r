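# Shared fixtures, all built in code.

# --- tiny deterministic videos ---------------------------------------------

const_video <- function(value, H = 8, W = 10, n = 5, fps = 8.66) {
  thermal_video(array(value, dim = c(H, W, n)), fps = fps)
}

# frame i (0-based) has constant temperature temp0 + slope * i
ramp_video <- function(H = 70, W = 70, n = 620, temp0 = 20, slope = 0.01,
                       fps = 8.66) {
  vals <- temp0 + slope * (seq_len(n) - 1)
  thermal_video(array(rep(vals, each = H * W), dim = c(H, W, n)), fps = fps)
}

# rectangle floor annotation for a small frame
toy_annotation <- function(W = 24, H = 24, margin = 2,
                           hab = c(0L, 149L), trial = c(155L, 299L)) {
  arena_annotation(
    floor_polygon = rbind(c(margin - 0.5, margin - 0.5),
                          c(W - margin - 0.5, margin - 0.5),
                          c(W - margin - 0.5, H - margin - 0.5),
                          c(margin - 0.5, H - margin - 0.5)),
    blackbody_polygon = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    habituation_interval = hab, trial_interval = trial,
    side_map = c(left = "social", right = "object"),
    preferred_side = "social")
}

# small random session for the detector oracle tests: 24 x 24 x n frames,
# textured floor, a roaming warm mouse disk, two decaying deposits
small_random_video <- function(seed, n = 300, H = 24, W = 24, fps = 8.66) {
  set.seed(seed)
  base <- matrix(25 + rnorm(H * W, 0, 0.15), H, W)
  floor_mask <- matrix(FALSE, H, W)
  floor_mask[3:(H - 2), 3:(W - 2)] <- TRUE
  base[!floor_mask] <- 23
  frames <- array(0, dim = c(H, W, n))
  pos <- c(runif(1, 6, W - 7), runif(1, 6, H - 7))
  ev <- data.frame(
    x = round(runif(2, 6, W - 7)), y = round(runif(2, 6, H - 7)),
    f = sort(round(runif(2, 40, n - 120))),
    peak = runif(2, 6, 9), tau = runif(2, 20, 45))
  for (i in seq_len(n)) {
    fr <- base
    for (e in 1:2) {
      u <- (i - 1 - ev$f[e]) / fps
      if (u >= 0) {
        delta <- ev$peak[e] * exp(-u / ev$tau[e]) - 0.4 * (1 - exp(-u / ev$tau[e]))
        ys <- max(1, ev$y[e] - 1):min(H, ev$y[e] + 1)
        xs <- max(1, ev$x[e] - 1):min(W, ev$x[e] + 1)
        fr[ys, xs] <- fr[ys, xs] + delta
      }
    }
    pos <- pos + rnorm(2, 0, 1.2)
    pos <- pmin(pmax(pos, 5), c(W, H) - 6)
    xs <- round(pos[1]) + (-2:2); ys <- round(pos[2]) + (-2:2)
    fr[ys + 1, xs + 1] <- pmax(fr[ys + 1, xs + 1], 34)
    frames[, , i] <- fr + rnorm(H * W, 0, 0.05)
  }
  list(video = thermal_video(frames, fps = fps), floor_mask = floor_mask)
}

# --- toy patch sequences for classifier tests ------------------------------

toy_sequence <- function(class, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- 78L; p <- 65L
  arr <- array(102, dim = c(p, p, np))
  prof <- switch(class,
                 urine = 10 * exp(-(0:77) / 30) * (0:77 >= 12),
                 feces = 8 * exp(-(0:77) / 8) * (0:77 >= 12),
                 background = rep(0, 78))
  sz <- if (class == "urine") 12L else 3L
  for (t in seq_len(np))
    arr[33 + (-sz:sz), 33 + (-sz:sz), t] <- 128 + prof[t] * 8
  arr <- pmin(pmax(arr + array(rnorm(p * p * np, 0, 2), dim = dim(arr)), 0), 255)
  structure(list(patches = arr, anchor = c(x = 50, y = 50, frame = 200),
                 valid = rep(TRUE, np)), class = "patch_sequence")
}

toy_example_set <- function(n_per_class = 20, seed = 5) {
  set.seed(seed)
  out <- list()
  for (cl in c("urine", "feces", "background"))
    for (i in seq_len(n_per_class))
      out[[length(out) + 1L]] <- list(label = cl, seq = toy_sequence(cl))
  out
}

# --- shared simulated easy sessions (memoized across test files) ------------
#
# The processed form drops the video (the memory-heavy part) and keeps the
# annotation, ground truth, detections and the featurized training
# examples extracted from the session.

.session_cache <- new.env(parent = emptyenv())

easy_session <- function(seed) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .session_cache)) {
    sim <- render_session(sim_preset("easy", seed = seed))
    video <- apply_calibration(sim$video, sim$calibration)
    det <- run_preliminary_detection(video, sim$annotation)
    id <- as.character(seed)
    full <- list(video = video, annotation = sim$annotation,
                 ground_truth = sim$ground_truth, detections = det, id = id)
    manifest <- build_training_set(setNames(list(full), id),
                                   seed = 1000L + seed)
    examples <- collect_training_examples(
      setNames(list(full), id), manifest,
      classifier_config(), positive_copies = 3L, seed = 2000L + seed)
    assign(key, list(annotation = sim$annotation,
                     ground_truth = sim$ground_truth,
                     detections = det, examples = examples, id = id),
           envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# re-render the calibrated video of a session (not cached; ~40 MB each)
easy_session_video <- function(seed) {
  sim <- render_session(sim_preset("easy", seed = seed))
  apply_calibration(sim$video, sim$calibration)
}

# recall of ground truth by detections within tolerance
recall_within <- function(gt, det, max_dist = 3, max_dt_s = 15, fps = 8.66) {
  if (nrow(gt) == 0L) return(NA_real_)
  hits <- vapply(seq_len(nrow(gt)), function(i) {
    d <- sqrt((det$x - gt$x[i])^2 + (det$y - gt$y[i])^2)
    dt <- abs(det$selected_frame - gt$frame[i]) / fps
    any(d <= max_dist & dt <= max_dt_s)
  }, logical(1))
  mean(hits)
}
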