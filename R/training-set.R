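# Training-set construction: positives at manual tags, random negatives
# away from any tag, hard negatives from unmatched preliminary detections.

# A candidate at (x_d, t_d) is "close" to a manual tag at (x_m, t_m) when
# distance < 25 px AND -10 s <= t_d - t_m <= 30 s.
is_close_to_tag <- function(x, y, t_s, gt, fps,
                            max_dist = 25, dt_lo = -10, dt_hi = 30) {
  if (nrow(gt) == 0L) return(FALSE)
  d <- sqrt((gt$x - x)^2 + (gt$y - y)^2)
  dt <- t_s - gt$frame / fps
  any(d < max_dist & dt >= dt_lo & dt <= dt_hi)
}

#' Build a classifier training manifest
#'
#' Collects, for each session: positive examples at every manual tag; 40
#' random negatives (labeled background) per session, half drawn in the
#' habituation stage and half in the trial stage, resampled (up to 1,000
#' attempts) whenever they land close in space and time to a manual tag
#' (distance < 25 px and -10 s <= t_d - t_m <= 30 s); and hard negatives:
#' preliminary detections that are not close to any manual tag.
#'
#' @param sessions A list of sessions, each a list with elements `video`
#'   ([thermal_video()]), `annotation` ([arena_annotation()]),
#'   `ground_truth` (tibble `label, frame, x, y`) and optionally
#'   `detections` (from [run_preliminary_detection()]; required for hard
#'   negatives) and `id`.
#' @param n_random_negatives Random negatives per session (default 40).
#' @param seed Integer seed making the sampling reproducible.
#' @return A tibble with columns `video_id`, `label`, `provenance`
#'   (`manual_positive`, `random_negative`, `hard_negative`), `x`, `y`,
#'   `frame`.
#' @export
build_training_set <- function(sessions, n_random_negatives = 40L,
                               seed = 1L) {
  set.seed(seed)
  out <- purrr::imap(sessions, function(s, idx) {
    id <- s$id %||% as.character(idx)
    fps <- s$video$fps
    gt <- s$ground_truth
    ann <- s$annotation
    floor_mask <- rasterize_polygon(ann$floor_polygon,
                                    s$video$height, s$video$width)
    floor_px <- which(floor_mask)
    pos <- if (nrow(gt) > 0)
      tibble(video_id = id, label = gt$label,
             provenance = "manual_positive", x = gt$x, y = gt$y,
             frame = gt$frame)
    else NULL

    neg_rows <- list()
    per_stage <- n_random_negatives %/% 2L
    for (stage in c("habituation", "trial")) {
      iv <- if (stage == "habituation") ann$habituation_interval
            else ann$trial_interval
      for (k in seq_len(per_stage)) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          px <- floor_px[sample.int(length(floor_px), 1L)]
          yx <- arrayInd(px, c(s$video$height, s$video$width))
          xx <- yx[2] - 1L; yy <- yx[1] - 1L
          fr <- sample.int(iv[2] - iv[1] + 1L, 1L) + iv[1] - 1L
          if (!is_close_to_tag(xx, yy, fr / fps, gt, fps)) {
            neg_rows[[length(neg_rows) + 1L]] <-
              tibble(video_id = id, label = "background",
                     provenance = "random_negative", x = xx, y = yy,
                     frame = as.integer(fr))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          abort("Could not place a random negative after 1,000 attempts.")
      }
    }

    hard <- NULL
    det <- s$detections
    if (!is.null(det) && nrow(det) > 0) {
      keep <- !purrr::map_lgl(seq_len(nrow(det)), function(i)
        is_close_to_tag(det$x[i], det$y[i], det$time_s[i], gt, fps))
      if (any(keep))
        hard <- tibble(video_id = id, label = "background",
                       provenance = "hard_negative",
                       x = det$x[keep], y = det$y[keep],
                       frame = det$selected_frame[keep])
    }
    dplyr::bind_rows(pos, dplyr::bind_rows(neg_rows), hard)
  })
  dplyr::bind_rows(out)
}

#' Augment a training example
#'
#' Draws one augmentation and applies it: positives get a time shift drawn
#' uniformly from [-3 s, +6 s] (compensating for offsets between the
#' manual tag time and the preliminary-detection time); all examples get a
#' spatial shift uniform on {-2..2}^2, an optional horizontal/vertical
#' flip, and a rotation from {0, 90, 180, 270} degrees. Time and spatial
#' shifts move the anchor and re-extract from the video; flips and
#' rotations act on the extracted patches. The label is preserved.
#'
#' @param example A list with `seq` (a `patch_sequence`), `label`,
#'   `provenance` and `anchor`.
#' @param video The session [thermal_video()] the example came from.
#' @param config [classifier_config()].
#' @return The augmented example (same shape).
#' @export
augment_example <- function(example, video, config = classifier_config()) {
  positive <- identical(example$provenance, "manual_positive")
  aug <- draw_augmentation(positive, video$fps)
  apply_augmentation(example, aug, video, config)
}

draw_augmentation <- function(positive, fps) {
  list(dt_frames = if (positive) round(runif(1, -3, 6) * fps) else 0L,
       dx = sample(-2:2, 1L), dy = sample(-2:2, 1L),
       flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
       rot = sample(c(0L, 90L, 180L, 270L), 1L))
}

apply_augmentation <- function(example, aug, video, config) {
  a <- example$seq$anchor
  x <- min(max(a[["x"]] + aug$dx, 0), video$width - 1)
  y <- min(max(a[["y"]] + aug$dy, 0), video$height - 1)
  fr <- a[["frame"]] + aug$dt_frames
  seq <- extract_patch_sequence(video, x, y, fr, config)
  seq$patches <- transform_patches(seq$patches, aug$flip_h, aug$flip_v, aug$rot)
  example$seq <- seq
  example
}

# flip/rotate every patch of the stack; rotation is counter-clockwise
transform_patches <- function(patches, flip_h = FALSE, flip_v = FALSE,
                              rot = 0L) {
  p <- dim(patches)[1]
  if (flip_h) patches <- patches[, p:1, , drop = FALSE]
  if (flip_v) patches <- patches[p:1, , , drop = FALSE]
  k <- (rot %/% 90L) %% 4L
  for (j in seq_len(k)) patches <- aperm(patches, c(2, 1, 3))[p:1, , , drop = FALSE]
  patches
}
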