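#' Preliminary-detector parameters
#'
#' Tuning parameters of the heuristic hot-blob detector. The defaults are
#' the operating point used throughout: a new deposit must rise more than
#' `dT_threshold` above the floor/background, must cool down by more than
#' `cooldown_min_C` and by more than `cooldown_frac` of its rise within the
#' `cooldown_horizon_s` that follows, and its blob (after morphological
#' closing) must contain between `min_blob_px` and `max_blob_px` pixels.
#'
#' @param dT_threshold Difference-image threshold in deg C (default 1.6).
#' @param mouse_threshold Mouse-mask threshold in deg C (default 1).
#' @param mouse_dilate_radius Disk radius (px) used to dilate the mouse
#'   difference mask (default 2).
#' @param close_radius Disk radius (px) of the morphological closing applied
#'   to the hot-blob mask, unifying nearby urine drops (default 4).
#' @param min_blob_px,max_blob_px Accepted blob size range in pixels
#'   (defaults 2 and 900).
#' @param cooldown_horizon_s Forward window (s) over which cooldown is
#'   measured (default 40).
#' @param cooldown_min_C Minimum cooldown in deg C (default 1.1).
#' @param cooldown_frac Minimum cooldown as a fraction of the temperature
#'   rise (default 0.5); kept at half, not more, because very large urine
#'   spots may take longer than the horizon to cool fully.
#' @param bg_init_s Length (s) of the initial per-pixel-minimum background
#'   window (default 20).
#' @param bg_window_s Two-element lag range (s) of the running background
#'   window (default `c(4, 5)`).
#' @param assoc_max_gap_s Maximum gap (s) for associating a blob with an
#'   existing track (default 30).
#' @param min_detected_frames Minimum number of frames a track must be
#'   detected in (default 2).
#' @param pixel_area_cm2 Area of one pixel in cm^2 (default 0.02).
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(dT_threshold = 1.6,
                            mouse_threshold = 1,
                            mouse_dilate_radius = 2,
                            close_radius = 4,
                            min_blob_px = 2,
                            max_blob_px = 900,
                            cooldown_horizon_s = 40,
                            cooldown_min_C = 1.1,
                            cooldown_frac = 0.5,
                            bg_init_s = 20,
                            bg_window_s = c(4, 5),
                            assoc_max_gap_s = 30,
                            min_detected_frames = 2,
                            pixel_area_cm2 = 0.02) {
  p <- as.list(environment())
  for (nm in setdiff(names(p), "bg_window_s"))
    stopifnot_scalar_number(p[[nm]], nm, positive = TRUE)
  if (length(bg_window_s) != 2L || bg_window_s[1] >= bg_window_s[2])
    abort("`bg_window_s` must be c(lo, hi) with lo < hi.")
  if (bg_window_s[2] > bg_init_s)
    abort("`bg_window_s[2]` must be <= `bg_init_s`.")
  if (min_blob_px > max_blob_px)
    abort("`min_blob_px` must be <= `max_blob_px`.")
  structure(p, class = "detector_params")
}

# Frame-lag window of the running background. The window spans lags of
# bg_window_s seconds plus one extra frame of margin, so that at the nominal
# 8.66 fps and the default c(4, 5) s window the lags are 36..44 frames
# (i.e. background for frame i is the minimum of the inpainted frames
# j in [i - 44, i - 36]).
bg_lag_window <- function(params, fps) {
  lo <- s_to_frames(params$bg_window_s[1], fps) + 1L
  hi <- s_to_frames(params$bg_window_s[2], fps) + 1L
  c(lo, hi)
}

#' Initial background image
#'
#' Per-pixel minimum over the first `bg_init_s` seconds of video. The mouse
#' is warmer than the floor and moves during this window, so every pixel
#' sees the floor at least once and the minimum is mouse-free.
#'
#' @param video A calibrated [thermal_video()].
#' @param params [detector_params()].
#' @return `H x W` background matrix.
#' @export
init_background <- function(video, params = detector_params()) {
  k <- s_to_frames(params$bg_init_s, video$fps)
  if (n_frames(video) < k)
    abort(sprintf("Video shorter than the %g s background init window.",
                  params$bg_init_s))
  apply(video$frames[, , seq_len(k), drop = FALSE], c(1, 2), min)
}

#' Mouse mask for one frame
#'
#' Thresholds the dilated difference between the frame and the running
#' background at `mouse_threshold`, labels 8-connected components, and
#' returns the component with the largest overlap with the arena floor
#' (ties to the smallest label; empty mask when no pixel passes).
#'
#' @param F_i Current frame (matrix, deg C).
#' @param B_prev Background of the previous frame.
#' @param floor_mask Logical arena-floor mask.
#' @param params [detector_params()].
#' @return Logical mouse mask.
#' @export
compute_mouse_mask <- function(F_i, B_prev, floor_mask,
                               params = detector_params()) {
  warm <- (F_i - B_prev) > params$mouse_threshold
  warm <- cpp_dilate_disk(warm, as.integer(params$mouse_dilate_radius))
  lab <- cpp_label8(warm)
  k <- max(lab)
  if (k == 0L) return(matrix(FALSE, nrow(F_i), ncol(F_i)))
  overlap <- tabulate(lab[floor_mask & lab > 0L], nbins = k)
  lab == which.max(overlap)  # which.max ties -> smallest label
}

#' Mouse-inpainted frame
#'
#' Replaces mouse pixels with their last known mouse-free values:
#' `N_i = N_prev` on the mouse mask, `F_i` elsewhere.
#'
#' @param N_prev Previous inpainted frame.
#' @param F_i Current frame.
#' @param M_i Current mouse mask.
#' @return Inpainted frame matrix.
#' @export
update_inpainted <- function(N_prev, F_i, M_i) {
  out <- F_i
  out[M_i] <- N_prev[M_i]
  out
}

#' Running background for one frame
#'
#' Per-pixel minimum of the mouse-inpainted frames at lags roughly 4-5 s in
#' the past (lags 36..44 frames at 8.66 fps); lags that reach before the
#' first frame use the initial background.
#'
#' @param N_history List of inpainted frames so far, `N_history[[j + 1]]`
#'   holding frame `j` (0-based).
#' @param i Current 0-based frame index.
#' @param fps Frame rate.
#' @param params [detector_params()].
#' @param B0 Initial background from [init_background()].
#' @return Background matrix `B_i`.
#' @export
update_background <- function(N_history, i, fps, params, B0) {
  w <- bg_lag_window(params, fps)
  acc <- NULL
  for (lag in seq.int(w[1], w[2])) {
    j <- i - lag
    Nj <- if (j < 0) B0 else N_history[[j + 1L]]
    acc <- if (is.null(acc)) Nj else pmin(acc, Nj)
  }
  acc
}

#' Arena-floor median temperature
#'
#' Median of the background over floor pixels not covered by the mouse in
#' this or the previous frame. For an even pixel count the lower median is
#' used.
#'
#' @param B_i Background matrix.
#' @param floor_mask Logical floor mask.
#' @param M_i,M_prev Current and previous mouse masks.
#' @return Scalar temperature (deg C).
#' @export
compute_floor_median <- function(B_i, floor_mask, M_i, M_prev) {
  sel <- floor_mask & !M_i & !M_prev
  if (!any(sel)) abort("No eligible floor pixels for the floor median.")
  lower_median(B_i[sel])
}

#' Difference image
#'
#' `D_i = F_i - max(T_floor, B_i)` pixel-wise. Flooring the background at
#' the floor median keeps the detection sensitivity uniform over darker
#' regions of the floor (e.g. patches of cooled-down urine).
#'
#' @param F_i Current frame.
#' @param B_i Background matrix.
#' @param T_floor Floor median from [compute_floor_median()].
#' @return Difference matrix.
#' @export
compute_difference <- function(F_i, B_i, T_floor) {
  F_i - pmax(B_i, T_floor)  # matrix first: pmax keeps its dim attributes
}

#' Cooldown image
#'
#' `CD_i = F_i` minus the per-pixel minimum of the frames in the following
#' `cooldown_horizon_s` seconds (window truncated at the end of the video).
#' Fresh deposits cool towards (and below) floor temperature, so their
#' cooldown is large; mouse and reflection pixels do not cool.
#'
#' @param video A [thermal_video()].
#' @param i 0-based frame index.
#' @param fps Frame rate (defaults to the video's).
#' @param params [detector_params()].
#' @return Cooldown matrix.
#' @export
compute_cooldown <- function(video, i, fps = video$fps,
                             params = detector_params()) {
  n <- n_frames(video)
  horizon <- s_to_frames(params$cooldown_horizon_s, fps)
  js <- seq.int(i, min(n - 1L, i + horizon))
  fut <- apply(video$frames[, , js + 1L, drop = FALSE], c(1, 2), min)
  frame_at(video, i) - fut
}

#' Hot-blob mask
#'
#' Pixels whose difference exceeds `dT_threshold`, that are outside the
#' current and previous mouse masks (the sensor's response time leaves
#' recently vacated pixels slightly bright), and whose cooldown exceeds
#' both `cooldown_min_C` and `cooldown_frac` of the difference. All
#' inequalities are strict.
#'
#' @param D_i Difference matrix.
#' @param M_i,M_prev Mouse masks.
#' @param CD_i Cooldown matrix.
#' @param params [detector_params()].
#' @return Logical hot-blob mask.
#' @export
compute_blob_mask <- function(D_i, M_i, M_prev, CD_i,
                              params = detector_params()) {
  (D_i > params$dT_threshold) & !M_i & !M_prev &
    (CD_i > params$cooldown_min_C) & (CD_i > params$cooldown_frac * D_i)
}

#' Refine the hot-blob mask into candidate blobs
#'
#' Applies a morphological closing (disk of `close_radius`) so nearby urine
#' drops unify into one blob, labels 8-connected components, and discards
#' components with any pixel outside the arena floor, components 8-adjacent
#' to (or overlapping) the current or previous mouse mask, and components
#' outside the `[min_blob_px, max_blob_px]` size range.
#'
#' @param BM_i Hot-blob mask from [compute_blob_mask()].
#' @param floor_mask Logical floor mask.
#' @param M_i,M_prev Mouse masks.
#' @param params [detector_params()].
#' @return List of candidate blobs, each an integer vector of 1-based
#'   linear pixel indices, in label order.
#' @export
refine_blobs <- function(BM_i, floor_mask, M_i, M_prev,
                         params = detector_params()) {
  if (!any(BM_i)) return(list())
  r <- as.integer(params$close_radius)
  closed <- cpp_erode_disk(cpp_dilate_disk(BM_i, r), r)
  lab <- cpp_label8(closed)
  k <- max(lab)
  if (k == 0L) return(list())
  near_mouse <- cpp_adjacent8(M_i | M_prev)
  out <- list()
  for (b in seq_len(k)) {
    px <- which(lab == b)
    if (length(px) < params$min_blob_px || length(px) > params$max_blob_px)
      next
    if (any(!floor_mask[px])) next
    if (any(near_mouse[px])) next
    out[[length(out) + 1L]] <- px
  }
  out
}

# ---- temporal association --------------------------------------------------

#' @rdname associate_blobs
#' @export
new_track_set <- function() list(tracks = list(), next_id = 1L)

#' Associate candidate blobs with existing tracks
#'
#' A candidate blob that intersects the union mask of a track whose last
#' detection is at most `assoc_max_gap_s` seconds old merges into that
#' track (mask union, frame appended); when several tracks qualify it
#' merges into the oldest (smallest first frame, ties to the smallest track
#' id). Otherwise the candidate starts a new track.
#'
#' @param track_set Track set from [new_track_set()] or a previous call.
#' @param candidates List of candidates, each a list with `px` (1-based
#'   linear pixel indices), `peak` (blob peak difference intensity) and
#'   `rep_px` (linear index of the peak pixel, row-major tie-break).
#' @param frame_i Current 0-based frame index.
#' @param fps Frame rate.
#' @param params [detector_params()].
#' @return Updated track set.
#' @export
associate_blobs <- function(track_set, candidates, frame_i, fps,
                            params = detector_params()) {
  for (cand in candidates) {
    best <- NULL
    for (tid in seq_along(track_set$tracks)) {
      tr <- track_set$tracks[[tid]]
      if ((frame_i - tr$last_frame) / fps > params$assoc_max_gap_s) next
      if (!any(cand$px %in% tr$union_px)) next
      if (is.null(best)) best <- tid
      else {
        bt <- track_set$tracks[[best]]
        if (tr$first_frame < bt$first_frame ||
            (tr$first_frame == bt$first_frame && tr$id < bt$id))
          best <- tid
      }
    }
    entry <- list(frame = frame_i, peak = cand$peak, rep_px = cand$rep_px)
    if (is.null(best)) {
      track_set$tracks[[length(track_set$tracks) + 1L]] <- list(
        id = track_set$next_id, first_frame = frame_i, last_frame = frame_i,
        union_px = cand$px, entries = list(entry))
      track_set$next_id <- track_set$next_id + 1L
    } else {
      tr <- track_set$tracks[[best]]
      tr$union_px <- union(tr$union_px, cand$px)
      tr$last_frame <- frame_i
      tr$entries[[length(tr$entries) + 1L]] <- entry
      track_set$tracks[[best]] <- tr
    }
  }
  track_set
}

#' Finalize tracks into preliminary detections
#'
#' Drops tracks detected in fewer than `min_detected_frames` frames. For
#' each remaining track the selected frame is the one with the maximal blob
#' peak intensity (earliest on ties) and the representative pixel is the
#' peak-intensity pixel of the blob in that frame (row-major tie-break).
#' The reported area is the union mask of the track.
#'
#' @param track_set Track set from [associate_blobs()].
#' @param params [detector_params()].
#' @param fps Frame rate.
#' @param dim_hw `c(H, W)` frame shape, to convert linear indices to x/y.
#' @return A tibble with columns `det_id`, `selected_frame`, `time_s`, `x`,
#'   `y`, `area_px`, `area_cm2`, `n_frames`, `first_frame`, `last_frame`
#'   (frames 0-based, coordinates 0-based pixels).
#' @export
finalize_tracks <- function(track_set, params, fps, dim_hw) {
  rows <- purrr::map(track_set$tracks, function(tr) {
    if (length(tr$entries) < params$min_detected_frames) return(NULL)
    peaks <- vapply(tr$entries, `[[`, numeric(1), "peak")
    sel <- which.max(peaks)  # which.max returns the earliest on ties
    e <- tr$entries[[sel]]
    yx <- arrayInd(e$rep_px, dim_hw)
    tibble(det_id = tr$id,
           selected_frame = e$frame,
           time_s = e$frame / fps,
           x = yx[2] - 1L, y = yx[1] - 1L,
           area_px = length(tr$union_px),
           area_cm2 = length(tr$union_px) * params$pixel_area_cm2,
           n_frames = length(tr$entries),
           first_frame = tr$first_frame,
           last_frame = tr$last_frame)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble(det_id = integer(), selected_frame = integer(),
                  time_s = double(), x = integer(), y = integer(),
                  area_px = integer(), area_cm2 = double(),
                  n_frames = integer(), first_frame = integer(),
                  last_frame = integer())
  out
}

# Peak intensity and representative pixel of a blob in the difference image.
blob_peak <- function(px, D, dim_hw) {
  vals <- D[px]
  mx <- max(vals)
  cand <- px[vals == mx]
  if (length(cand) > 1L) {
    yx <- arrayInd(cand, dim_hw)
    cand <- cand[order(yx[, 1], yx[, 2])][1L]
  }
  list(peak = mx, rep_px = cand[1L])
}

# Run the detector over one stage (a frame-contiguous sub-video).
# The per-frame loop runs in compiled code (see src/detector_core.cpp); the
# exported stage operations above implement the identical arithmetic one
# step at a time and the test suite holds the two paths exactly equal.
# Returns the finalized detections (frames 0-based and stage-local) and,
# optionally, every per-frame intermediate.
run_predetect_stage <- function(video, floor_mask, params,
                                keep_intermediates = FALSE) {
  n <- n_frames(video)
  fps <- video$fps
  H <- video$height; W <- video$width
  w <- bg_lag_window(params, fps)
  flat <- matrix(video$frames, nrow = H * W, ncol = n)
  res <- cpp_run_stage(
    flat, H, W, floor_mask,
    dT_threshold = params$dT_threshold,
    mouse_threshold = params$mouse_threshold,
    mouse_dilate_radius = as.integer(params$mouse_dilate_radius),
    close_radius = as.integer(params$close_radius),
    min_blob_px = as.integer(params$min_blob_px),
    max_blob_px = as.integer(params$max_blob_px),
    cooldown_min_C = params$cooldown_min_C,
    cooldown_frac = params$cooldown_frac,
    bg_init_frames = s_to_frames(params$bg_init_s, fps),
    lag_lo = w[1], lag_hi = w[2],
    horizon_frames = s_to_frames(params$cooldown_horizon_s, fps),
    keep_intermediates = keep_intermediates)

  tracks <- new_track_set()
  for (cand in res$candidates) {
    tracks <- associate_blobs(
      tracks,
      list(list(px = cand$px, peak = cand$peak, rep_px = cand$rep_px)),
      cand$frame, fps, params)
  }
  det <- finalize_tracks(tracks, params, fps, c(H, W))

  keep <- NULL
  if (keep_intermediates) {
    to_frames <- function(m, logical = FALSE) {
      lapply(seq_len(n), function(i) {
        fr <- matrix(m[, i], H, W)
        if (logical) fr > 0.5 else fr
      })
    }
    keep <- list(M = to_frames(res$M, logical = TRUE),
                 N = to_frames(res$N), B = to_frames(res$B),
                 T_floor = as.numeric(res$T_floor),
                 D = to_frames(res$D), CD = to_frames(res$CD),
                 BM = to_frames(res$BM, logical = TRUE))
  }
  list(detections = det, tracks = tracks, intermediates = keep)
}

#' Run preliminary hot-blob detection on a session
#'
#' Orchestrates the full heuristic detector: background initialisation and
#' running update with mouse inpainting, difference and cooldown images,
#' hot-blob masking and refinement, temporal association and track
#' finalization. The habituation and trial stages are processed
#' independently (the arena may shift slightly when stimuli are
#' introduced); detection ids are unique across the session.
#'
#' @param video A calibrated [thermal_video()] covering the whole session.
#' @param annotation An [arena_annotation()].
#' @param params [detector_params()].
#' @param stages Which stages to process.
#' @return A tibble of preliminary detections with columns `det_id`,
#'   `stage`, `selected_frame`, `time_s`, `x`, `y`, `area_px`, `area_cm2`,
#'   `n_frames`, `first_frame`, `last_frame`. Frames are 0-based indices
#'   into the session video; `time_s` is the selected frame's time.
#' @export
run_preliminary_detection <- function(video, annotation,
                                      params = detector_params(),
                                      stages = c("habituation", "trial")) {
  stopifnot(inherits(video, "thermal_video"),
            inherits(annotation, "arena_annotation"))
  floor_mask <- rasterize_polygon(annotation$floor_polygon,
                                  video$height, video$width)
  out <- list()
  offset_id <- 0L
  for (stage in stages) {
    iv <- switch(stage,
                 habituation = annotation$habituation_interval,
                 trial = annotation$trial_interval,
                 abort(sprintf("Unknown stage '%s'.", stage)))
    if (iv[2] >= n_frames(video))
      abort("Stage interval exceeds the video length.")
    sub_frames <- video$frames[, , (iv[1] + 1L):(iv[2] + 1L), drop = FALSE]
    # already-validated frames: skip the constructor's finiteness scan
    sub <- structure(
      list(frames = sub_frames, fps = video$fps,
           timestamps = (seq_len(dim(sub_frames)[3]) - 1) / video$fps,
           height = video$height, width = video$width),
      class = "thermal_video")
    res <- run_predetect_stage(sub, floor_mask, params)
    det <- res$detections
    if (nrow(det) > 0) {
      det$det_id <- det$det_id + offset_id
      det$selected_frame <- det$selected_frame + iv[1]
      det$first_frame <- det$first_frame + iv[1]
      det$last_frame <- det$last_frame + iv[1]
      det$time_s <- det$selected_frame / video$fps
      offset_id <- max(det$det_id)
    }
    det$stage <- rep(stage, nrow(det))
    out[[stage]] <- det
  }
  dplyr::bind_rows(out)[, c("det_id", "stage", "selected_frame", "time_s",
                            "x", "y", "area_px", "area_cm2", "n_frames",
                            "first_frame", "last_frame")]
}

#' Read and write detection tables
#'
#' @param detections Detections tibble from [run_preliminary_detection()]
#'   (optionally with classifier columns).
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  write_csv_stable(detections, path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}
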