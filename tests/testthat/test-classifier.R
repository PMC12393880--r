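test_that("patch sequences have 78 patches at frames i + 8k with padding at 102", {
  cfg <- classifier_config()
  v <- ramp_video(H = 70, W = 70, n = 620)  # frame i reads 20 + 0.01 i degC
  anchor_frame <- 150L
  seq <- extract_patch_sequence(v, 35, 35, anchor_frame, cfg)
  expect_equal(dim(seq$patches), c(65, 65, 78))
  expect_length(seq$valid, 78)

  # every valid patch is the normalized constant of frame i + 8k
  for (t in seq_len(78)) {
    k <- cfg$k_range[t]
    fi <- anchor_frame + 8L * k
    if (fi < 0 || fi >= 620) {
      expect_false(seq$valid[t])
      expect_true(all(seq$patches[, , t] == 102))
    } else {
      expect_true(seq$valid[t])
      expected <- (20 + 0.01 * fi - 10) / 30 * 255
      expect_equal(seq$patches[33, 33, t], expected, tolerance = 1e-10)
    }
  }

  # event at frame 0: the 12 look-back patches are uniform padding at 102
  seq0 <- extract_patch_sequence(v, 35, 35, 0L, cfg)
  expect_true(all(seq0$patches[, , 1:12] == 102))
  expect_false(any(seq0$valid[1:12]))

  # the linear map: 25 degC -> 127.5; 45 degC -> clipped to 255
  v2 <- const_video(25, H = 70, W = 70, n = 1)
  s2 <- extract_patch_sequence(v2, 35, 35, 0L, cfg)
  expect_equal(s2$patches[33, 33, 13], 127.5)
  v3 <- const_video(45, H = 70, W = 70, n = 1)
  s3 <- extract_patch_sequence(v3, 35, 35, 0L, cfg)
  expect_equal(s3$patches[33, 33, 13], 255)
  v4 <- const_video(5, H = 70, W = 70, n = 1)
  s4 <- extract_patch_sequence(v4, 35, 35, 0L, cfg)
  expect_equal(s4$patches[33, 33, 13], 0)

  expect_error(extract_patch_sequence(v, 80, 35, 0L, cfg), "outside")
})

test_that("patch extraction is translation-consistent away from borders", {
  cfg <- classifier_config()
  set.seed(11)
  H <- 200; W <- 200; n <- 3
  arr <- array(runif(H * W * n, 15, 35), dim = c(H, W, n))
  dx <- 4L; dy <- 7L
  shifted <- array(15, dim = c(H, W, n))
  shifted[(1 + dy):H, (1 + dx):W, ] <- arr[1:(H - dy), 1:(W - dx), ]
  v1 <- thermal_video(arr); v2 <- thermal_video(shifted)
  s1 <- extract_patch_sequence(v1, 100, 100, 0L, cfg)
  s2 <- extract_patch_sequence(v2, 100 + dx, 100 + dy, 0L, cfg)
  expect_equal(s1$patches[, , 13], s2$patches[, , 13])
})

test_that("triple packing is invertible with temporal channel order", {
  seq <- toy_sequence("urine", seed = 1)
  tri <- pack_triples(seq)
  expect_equal(dim(tri), c(65, 65, 3, 26))
  expect_equal(unpack_triples(tri), seq$patches)
  # distinct constant patches land in the right channels
  p <- array(0, dim = c(5, 5, 6))
  p[, , 2] <- 100; p[, , 3] <- 200
  tr <- pack_triples(p)
  expect_equal(tr[1, 1, , 1], c(0, 100, 200))
})

test_that("position-time encoding is a 256-vector, injective in t, deterministic", {
  cfg <- classifier_config()
  set.seed(3)
  w <- init_encoding_weights(cfg)
  e1 <- position_time_encoding(0.3, 0.7, 0.1, w, cfg)
  expect_length(e1, 256)
  e2 <- position_time_encoding(0.3, 0.7, 0.9, w, cfg)
  r1 <- thermark:::position_time_encoding_raw(0.3, 0.7, 0.1, cfg)
  r2 <- thermark:::position_time_encoding_raw(0.3, 0.7, 0.9, cfg)
  expect_length(r1, 384)
  expect_false(isTRUE(all.equal(r1, r2)))
  expect_identical(e1, position_time_encoding(0.3, 0.7, 0.1, w, cfg))
})

test_that("augmentation preserves labels, keeps shifts in range, and rot90^4 = id", {
  cfg <- classifier_config()
  v <- ramp_video(H = 80, W = 80, n = 630)
  ex <- list(label = "urine", provenance = "manual_positive",
             seq = extract_patch_sequence(v, 40, 40, 100L, cfg))

  # identity augmentation is the identity
  id_aug <- list(dt_frames = 0L, dx = 0L, dy = 0L, flip_h = FALSE,
                 flip_v = FALSE, rot = 0L)
  ex_id <- thermark:::apply_augmentation(ex, id_aug, v, cfg)
  expect_equal(ex_id$seq$patches, ex$seq$patches)

  # rotation by 90 applied four times is the identity
  p <- ex$seq$patches
  for (i in 1:4) p <- thermark:::transform_patches(p, rot = 90L)
  expect_equal(p, ex$seq$patches)

  # drawn augmentations stay in the documented ranges and keep the label
  set.seed(21)
  for (i in 1:200) {
    aug <- thermark:::draw_augmentation(TRUE, 8.66)
    expect_true(aug$dx %in% -2:2 && aug$dy %in% -2:2)
    # the drawn seconds are in [-3, 6]; frame rounding adds up to half a frame
    expect_gte(aug$dt_frames / 8.66, -3 - 0.5 / 8.66)
    expect_lte(aug$dt_frames / 8.66, 6 + 0.5 / 8.66)
    expect_true(aug$rot %in% c(0L, 90L, 180L, 270L))
  }
  set.seed(22)
  ex2 <- augment_example(ex, v, cfg)
  expect_identical(ex2$label, "urine")
})

test_that("training-set construction follows the closeness rule", {
  # closeness predicate boundaries
  gt <- tibble::tibble(label = "urine", frame = 100L, x = 50, y = 50)
  close <- thermark:::is_close_to_tag
  fps <- 8.66
  expect_true(close(50 + 24, 50, 100 / fps, gt, fps))   # 24 px, dt 0
  expect_false(close(50 + 30, 50, 100 / fps, gt, fps))  # 30 px, dt 0
  expect_false(close(50 + 25, 50, 100 / fps, gt, fps))  # exactly 25 px: not close
  expect_true(close(50, 50, 100 / fps + 30, gt, fps))   # dt exactly +30 s
  expect_false(close(50, 50, 100 / fps + 30.1, gt, fps))
  expect_true(close(50, 50, 100 / fps - 10, gt, fps))   # dt exactly -10 s
  expect_false(close(50, 50, 100 / fps - 10.1, gt, fps))

  # a tag-free session yields 40 random negatives + every detection as a
  # hard negative
  s <- easy_session(101)
  video_stub <- structure(list(frames = array(25, dim = c(120, 160, 1)),
                               fps = 8.66, timestamps = 0,
                               height = 120L, width = 160L),
                          class = "thermal_video")
  sess <- list(video = video_stub, annotation = s$annotation,
               ground_truth = s$ground_truth[0, ],
               detections = s$detections, id = "x")
  man <- build_training_set(list(x = sess), seed = 31)
  expect_equal(sum(man$provenance == "random_negative"), 40)
  expect_equal(sum(man$provenance == "hard_negative"), nrow(s$detections))
  expect_true(all(man$label == "background"))

  # with tags: half the random negatives per stage, none close to a tag
  sess$ground_truth <- s$ground_truth
  man2 <- build_training_set(list(x = sess), seed = 31)
  neg <- man2[man2$provenance == "random_negative", ]
  expect_equal(nrow(neg), 40)
  hab_iv <- s$annotation$habituation_interval
  expect_equal(sum(neg$frame <= hab_iv[2]), 20)
  for (i in seq_len(nrow(neg)))
    expect_false(close(neg$x[i], neg$y[i], neg$frame[i] / fps,
                       s$ground_truth, fps))
  # true detections are all close to tags here -> no hard negatives
  expect_equal(sum(man2$provenance == "hard_negative"), 0)
  # sampling is reproducible from the seed
  expect_identical(man2, build_training_set(list(x = sess), seed = 31))
})

test_that("the tiny classifier learns a separable set and is deterministic", {
  cfg <- classifier_config()
  exs <- toy_example_set(n_per_class = 20, seed = 5)
  sched <- tiny_training_schedule(epochs = 30, drop_after = 25)
  mod <- train_classifier(exs, cfg, sched, seed = 2, dim_hw = c(120, 160))

  # loss strictly decreases over the first 10 epochs
  expect_true(all(diff(mod$history$loss[1:10]) < 0))

  # >= 0.95 training accuracy after 30 epochs
  preds <- vapply(exs, function(e) classify_detection(mod, e$seq)$label, "")
  truth <- vapply(exs, `[[`, "", "label")
  expect_gte(mean(preds == truth), 0.95)

  # held-out synthetic sequences classified with >= 0.9 accuracy
  held <- toy_example_set(n_per_class = 10, seed = 77)
  preds_h <- vapply(held, function(e) classify_detection(mod, e$seq)$label, "")
  expect_gte(mean(preds_h == vapply(held, `[[`, "", "label")), 0.9)

  # scores form a probability vector; inference is deterministic
  sc <- classify_detection(mod, held[[1]]$seq)
  expect_equal(sum(sc$scores), 1, tolerance = 1e-6)
  expect_identical(sc, classify_detection(mod, held[[1]]$seq))

  # training is deterministic under a fixed seed
  mod2 <- train_classifier(exs, cfg, sched, seed = 2, dim_hw = c(120, 160))
  expect_identical(tail(mod$history$loss, 1), tail(mod2$history$loss, 1))

  # the schedule and config round-trip into the model card
  dir <- withr::local_tempdir()
  write_model(mod, file.path(dir, "m"))
  card <- jsonlite::fromJSON(file.path(dir, "m.card.json"))
  expect_equal(card$backbone, "tiny")
  expect_equal(card$schedule$epochs, 30)
  expect_equal(card$seed, 2)
  mod3 <- read_model(file.path(dir, "m"))
  expect_equal(mod3$params, mod$params)

  # a missing class is refused
  expect_error(train_classifier(exs[1:20], cfg, sched, dim_hw = c(120, 160)),
               "lacks")
})

test_that("the reference backbone is documented but not trainable here", {
  cfg <- classifier_config(backbone = "reference")
  expect_error(train_classifier(toy_example_set(2), cfg), "tiny")
})
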