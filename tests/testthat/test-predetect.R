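# Unit tests of the detector stage operations against small hand-built
# oracles. The full-pipeline equivalence against the naive reference runs
# in test-acceptance.R.

fps <- 8.66

test_that("initial background is the per-pixel minimum of the first 20 s", {
  p <- detector_params()
  # static video
  v <- const_video(25, H = 6, W = 6, n = 180)
  expect_equal(init_background(v, p), matrix(25, 6, 6))

  # moving warm blob: every pixel covered < 20 s -> floor everywhere
  frames <- array(25, dim = c(6, 30, 180))
  for (i in seq_len(180)) {
    x <- (i %% 30) + 1
    frames[3, x, i] <- 35
  }
  v2 <- thermal_video(frames, fps = fps)
  expect_equal(init_background(v2, p), matrix(25, 6, 30))

  # per-pixel min oracle on random frames
  set.seed(2)
  arr <- array(runif(6 * 6 * 200, 20, 30), dim = c(6, 6, 200))
  k <- round(20 * fps)
  expect_equal(init_background(thermal_video(arr, fps = fps), p),
               apply(arr[, , 1:k], c(1, 2), min))

  expect_error(init_background(const_video(25, n = 90), p), "shorter")
})

test_that("mouse mask keeps the component with maximal floor overlap", {
  p <- detector_params()
  H <- 20; W <- 20
  B <- matrix(25, H, W)
  floor_mask <- matrix(FALSE, H, W); floor_mask[3:18, 3:18] <- TRUE

  # nothing above threshold -> empty mask
  expect_false(any(compute_mouse_mask(B + 0.5, B, floor_mask, p)))

  # one warm region -> that region dilated by the disk of radius 2
  Fi <- B; Fi[8:10, 8:10] <- 28
  M <- compute_mouse_mask(Fi, B, floor_mask, p)
  expected <- ref_dilate(Fi - B > 1, 2)
  expect_identical(M, expected)

  # two components: the one overlapping more floor wins
  Fi2 <- B
  Fi2[4:9, 4:9] <- 28       # 36 px on floor (before dilation)
  Fi2[1:2, 14:17] <- 28     # mostly off floor
  M2 <- compute_mouse_mask(Fi2, B, floor_mask, p)
  expect_true(M2[6, 6]); expect_false(M2[1, 15])
})

test_that("inpainting blends previous values under the mouse mask", {
  N_prev <- matrix(1, 4, 4); Fi <- matrix(2, 4, 4)
  none <- matrix(FALSE, 4, 4); all_m <- matrix(TRUE, 4, 4)
  expect_equal(update_inpainted(N_prev, Fi, none), Fi)
  expect_equal(update_inpainted(N_prev, Fi, all_m), N_prev)
  chk <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(update_inpainted(N_prev, Fi, chk), ifelse(chk, N_prev, Fi))
})

test_that("running background uses inpainted frames at lags 36..44 frames", {
  p <- detector_params()
  B0 <- matrix(30, 3, 3)
  # distinct constant N_j so the selected window is identifiable
  N_hist <- lapply(0:99, function(j) matrix(100 + j, 3, 3))
  B <- update_background(N_hist, i = 60, fps, p, B0)
  # window must be j in [60 - 44, 60 - 36] = [16, 24]; min = N_16
  expect_equal(B, matrix(116, 3, 3))

  # one frame in the window lowered at one pixel
  N_hist[[20 + 1]][2, 2] <- 50
  B2 <- update_background(N_hist, 60, fps, p, B0)
  expect_equal(B2[2, 2], 50)
  expect_equal(B2[1, 1], 116)

  # i = 0: the window is entirely before the video -> B0
  expect_equal(update_background(N_hist, 0, fps, p, B0), B0)
})

test_that("floor median uses the lower median of eligible pixels", {
  B <- matrix(24, 3, 3)
  floor_mask <- matrix(TRUE, 3, 3)
  none <- matrix(FALSE, 3, 3)
  expect_equal(compute_floor_median(B, floor_mask, none, none), 24)

  # {23, 24, 100} with the 100 masked by the mouse -> {23, 24} -> 23
  B2 <- matrix(23, 3, 3); B2[1, 2] <- 24; B2[2, 2] <- 100
  fl <- matrix(FALSE, 3, 3); fl[1, 1] <- TRUE; fl[1, 2] <- TRUE; fl[2, 2] <- TRUE
  M <- matrix(FALSE, 3, 3); M[2, 2] <- TRUE
  expect_equal(compute_floor_median(B2, fl, M, none), 23)

  # sort-based oracle on random values
  set.seed(4)
  B3 <- matrix(runif(9, 20, 30), 3, 3)
  expect_equal(compute_floor_median(B3, floor_mask, none, none),
               sort(B3)[ceiling(9 / 2)])

  expect_error(compute_floor_median(B, floor_mask, matrix(TRUE, 3, 3), none),
               "eligible")
})

test_that("difference image floors the background at the arena median", {
  Fi <- matrix(c(25, 27, 23, 26), 2, 2)
  B <- matrix(c(24, 24, 21, 27), 2, 2)
  Tf <- 24
  D <- compute_difference(Fi, B, Tf)
  # where B >= T: D = F - B; where B < T (cooled urine): D = F - T
  expect_equal(D, Fi - pmax(B, Tf))
  expect_equal(D[1, 2], 23 - 24)  # dark pixel measured against T, not B
  expect_equal(compute_difference(pmax(B, Tf), B, Tf), matrix(0, 2, 2))
})

test_that("cooldown is the drop to the forward-window minimum", {
  p <- detector_params()
  n <- 400
  frames <- array(25, dim = c(2, 2, n))
  # pixel (1,1) decays 36 -> 25 starting at frame 10
  decay_start <- 10
  for (i in decay_start:n)
    frames[1, 1, i] <- 25 + 11 * exp(-(i - decay_start) / 20)
  v <- thermal_video(frames, fps = fps)
  CD <- compute_cooldown(v, decay_start - 1, fps, p)
  expect_equal(CD[2, 2], 0)  # constant pixel
  horizon <- round(40 * fps)
  expect_equal(CD[1, 1],
               frames[1, 1, decay_start] -
                 min(frames[1, 1, decay_start:(decay_start + horizon)]))
  # last frame: the window is the frame itself
  expect_equal(compute_cooldown(v, n - 1, fps, p), matrix(0, 2, 2))
})

test_that("hot-blob mask applies all predicates with strict inequalities", {
  p <- detector_params()
  none <- matrix(FALSE, 1, 3)
  D <- matrix(c(2.0, 2.0, 2.0), 1, 3)
  CD <- matrix(c(1.5, 1.0, 1.5), 1, 3)
  M <- none; M_prev <- matrix(c(FALSE, FALSE, TRUE), 1, 3)
  BM <- compute_blob_mask(D, M, M_prev, CD, p)
  expect_identical(as.vector(BM), c(TRUE, FALSE, FALSE))
  # boundary: CD exactly 1.1 or exactly half of D fails (strict)
  expect_false(compute_blob_mask(matrix(2), matrix(FALSE), matrix(FALSE),
                                 matrix(1.1), p)[1, 1])
  expect_false(compute_blob_mask(matrix(3), matrix(FALSE), matrix(FALSE),
                                 matrix(1.5), p)[1, 1])
})

test_that("blob refinement closes, filters by size, floor and mouse adjacency", {
  p <- detector_params()
  H <- 40; W <- 40
  floor_mask <- matrix(TRUE, H, W)
  none <- matrix(FALSE, H, W)

  # single 1-px blob -> discarded
  BM <- none; BM[10, 10] <- TRUE
  expect_length(refine_blobs(BM, floor_mask, none, none, p), 0)

  # 900-px blob retained, 901-px blob discarded
  BM2 <- none; BM2[1:30, 1:30] <- TRUE
  expect_length(refine_blobs(BM2, floor_mask, none, none, p), 1)
  BM3 <- BM2; BM3[31, 1] <- TRUE
  expect_length(refine_blobs(BM3, floor_mask, none, none, p), 0)

  # two nearby 3x3 drops (4-px gap) merge under the closing; the same
  # drops 6 px apart stay separate
  BM4 <- none
  BM4[19:21, 10:12] <- TRUE
  BM4[19:21, 17:19] <- TRUE
  blobs <- refine_blobs(BM4, floor_mask, none, none, p)
  expect_length(blobs, 1)
  closed_oracle <- ref_erode(ref_dilate(BM4, 4), 4)
  expect_setequal(blobs[[1]], which(closed_oracle))
  BM4b <- none
  BM4b[19:21, 10:12] <- TRUE
  BM4b[19:21, 19:21] <- TRUE
  expect_length(refine_blobs(BM4b, floor_mask, none, none, p), 2)

  # blob overlapping a pixel outside the floor is discarded
  fl2 <- floor_mask; fl2[, 1:11] <- FALSE
  BM5 <- none; BM5[20, 10:14] <- TRUE
  expect_length(refine_blobs(BM5, fl2, none, none, p), 0)

  # blob 8-adjacent to the mouse mask is discarded
  M <- none; M[21, 15] <- TRUE
  BM6 <- none; BM6[20, 10:14] <- TRUE
  expect_length(refine_blobs(BM6, floor_mask, M, none, p), 0)
})

test_that("temporal association merges overlapping blobs within 30 s", {
  p <- detector_params()
  cand <- function(px) list(px = px, peak = 2, rep_px = px[1])
  ts <- new_track_set()
  ts <- associate_blobs(ts, list(cand(c(10L, 11L))), 0L, fps, p)
  # overlap 10 s later -> merged
  ts <- associate_blobs(ts, list(cand(c(11L, 12L))), round(10 * fps), fps, p)
  expect_length(ts$tracks, 1)
  expect_setequal(ts$tracks[[1]]$union_px, c(10L, 11L, 12L))

  # overlap 31 s after the last detection -> new track
  last <- ts$tracks[[1]]$last_frame
  ts <- associate_blobs(ts, list(cand(c(12L, 13L))),
                        last + round(31 * fps), fps, p)
  expect_length(ts$tracks, 2)

  # disjoint mask -> new track
  ts <- associate_blobs(ts, list(cand(c(500L))), last + 1L, fps, p)
  expect_length(ts$tracks, 3)

  # a candidate intersecting two live tracks merges into the oldest
  ts2 <- new_track_set()
  ts2 <- associate_blobs(ts2, list(cand(c(1L, 2L))), 0L, fps, p)
  ts2 <- associate_blobs(ts2, list(cand(c(5L, 6L))), 5L, fps, p)
  ts2 <- associate_blobs(ts2, list(cand(c(2L, 3L, 4L, 5L))), 10L, fps, p)
  expect_length(ts2$tracks, 2)
  expect_setequal(ts2$tracks[[1]]$union_px, 1:5)
})

test_that("track finalization selects the peak frame and representative pixel", {
  p <- detector_params()
  ts <- new_track_set()
  mk <- function(frame, peak, rep_px, px = c(7L, 8L))
    list(px = px, peak = peak, rep_px = rep_px)
  ts <- associate_blobs(ts, list(mk(0L, 2.0, 7L)), 0L, fps, p)
  ts <- associate_blobs(ts, list(mk(1L, 3.5, 8L)), 1L, fps, p)
  ts <- associate_blobs(ts, list(mk(2L, 3.5, 7L)), 2L, fps, p)
  det <- finalize_tracks(ts, p, fps, c(10L, 10L))
  expect_equal(nrow(det), 1)
  expect_equal(det$selected_frame, 1L)        # earliest of the tied peaks
  expect_equal(det$x, 0L); expect_equal(det$y, 7L)  # linear index 8 -> (y=7,x=0)
  expect_equal(det$area_px, 2L)
  expect_equal(det$area_cm2, 2 * 0.02)        # pixel area 0.02 cm^2
  expect_equal(det$time_s, 1 / fps)

  # single-frame tracks are dropped
  ts1 <- associate_blobs(new_track_set(), list(mk(0L, 2, 7L)), 0L, fps, p)
  expect_equal(nrow(finalize_tracks(ts1, p, fps, c(10L, 10L))), 0)
})

test_that("detections are invariant to appending static frames (horizon saturation)", {
  sv <- small_random_video(31, n = 260)
  res1 <- thermark:::run_predetect_stage(sv$video, sv$floor_mask,
                                         detector_params())
  last <- sv$video$frames[, , 260]
  extended <- array(c(sv$video$frames, rep(last, 400)),
                    dim = c(24, 24, 660))
  res2 <- thermark:::run_predetect_stage(thermal_video(extended, fps = 8.66),
                                         sv$floor_mask, detector_params())
  expect_equal(as.data.frame(res1$detections),
               as.data.frame(res2$detections))
})

test_that("an event-free arena yields zero detections", {
  cfg <- sim_preset("easy", seed = 901, n_urine = 0, n_feces = 0)
  sim <- render_session(cfg)
  det <- run_preliminary_detection(
    apply_calibration(sim$video, sim$calibration), sim$annotation)
  expect_equal(nrow(det), 0)
})

test_that("a clean simulated session is recovered with tight localization", {
  s <- easy_session(101)
  expect_equal(nrow(s$detections), nrow(s$ground_truth))
  expect_equal(recall_within(s$ground_truth, s$detections), 1.0)
  expect_true(all(s$detections$stage %in% c("habituation", "trial")))
  expect_true(all(s$detections$n_frames >= 2))
})
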