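fps <- 8.66

det_row <- function(id, label, t, x, y)
  tibble::tibble(det_id = id, label = label, time_s = t, x = x, y = y)

test_that("matching tolerances are inclusive at 20 px and 15 s", {
  gt <- tibble::tibble(label = "urine", frame = 0L, x = 30, y = 30)
  det <- det_row(1L, "urine", 15, 50, 30)  # exactly 20 px, 15 s
  m <- match_events(gt, det, fps = fps)
  expect_equal(m$gt$status, "correct")
  expect_equal(m$det$role, "absorbed")

  det2 <- det_row(1L, "urine", 15.01, 50, 30)
  expect_equal(match_events(gt, det2, fps = fps)$gt$status, "missed")
  det3 <- det_row(1L, "urine", 15, 50.1, 30)
  expect_equal(match_events(gt, det3, fps = fps)$gt$status, "missed")
})

test_that("only-wrong-label windows record the closest as a misclassification", {
  gt <- tibble::tibble(label = "urine", frame = 0L, x = 30, y = 30)
  det <- dplyr::bind_rows(det_row(1L, "feces", 2, 35, 30),
                          det_row(2L, "feces", 1, 40, 30))
  m <- match_events(gt, det, fps = fps)
  expect_equal(m$gt$status, "misclassified")
  expect_equal(m$gt$pred_label, "feces")
  expect_equal(m$det$role, c("misclassification", "false_alarm"))

  # ties on distance break by |dt|, then det_id
  det2 <- dplyr::bind_rows(det_row(1L, "feces", 5, 35, 30),
                           det_row(2L, "feces", 2, 25, 30))
  m2 <- match_events(gt, det2, fps = fps)
  expect_equal(m2$det$role, c("false_alarm", "misclassification"))

  # classification into background counts as a misclassification, and an
  # unclaimed background detection is not a false alarm
  det3 <- dplyr::bind_rows(det_row(1L, "background", 0, 31, 30),
                           det_row(2L, "background", 50, 100, 100))
  m3 <- match_events(gt, det3, fps = fps)
  expect_equal(m3$gt$pred_label, "background")
  expect_equal(m3$det$role, c("misclassification", "background"))
})

test_that("same-label duplicates inside one window are absorbed", {
  gt <- tibble::tibble(label = "feces", frame = 87L, x = 30, y = 30)
  det <- dplyr::bind_rows(det_row(1L, "feces", 10, 31, 30),
                          det_row(2L, "feces", 12, 28, 31))
  m <- match_events(gt, det, fps = fps)
  cm <- build_confusion(m)
  expect_equal(cm["feces", "feces"], 1L)
  expect_equal(sum(cm[, "background"]), 0L)  # no false alarms
})

test_that("the confusion matrix tallies correct, miss, misclassification, FA", {
  # perfect detection of 5 urine + 5 feces, spaced beyond the matching
  # tolerances so no window contains a neighbour
  gt <- tibble::tibble(label = rep(c("urine", "feces"), each = 5),
                       frame = as.integer(seq(0, 9) * 200),
                       x = rep(c(10, 40, 70, 100, 130), 2),
                       y = rep(c(20, 60), each = 5))
  det <- tibble::tibble(det_id = 1:10, label = gt$label,
                        time_s = gt$frame / fps, x = gt$x, y = gt$y)
  cm <- build_confusion(match_events(gt, det, fps = fps))
  expect_equal(cm["urine", "urine"], 5L)
  expect_equal(cm["feces", "feces"], 5L)
  expect_equal(sum(cm) - 10L, 0L)

  # an undetected event lands in the miss row under its true label
  cm2 <- build_confusion(match_events(gt[1, ], det[0, ], fps = fps))
  expect_equal(cm2["miss", "urine"], 1L)

  report <- score_report(cm)
  expect_equal(report$scores$f1, c(1, 1))
  expect_equal(report$mean_f1, 1)
})

test_that("scores follow the precision/recall/F1 arithmetic", {
  cm <- matrix(0L, 4, 3, dimnames = list(
    pred = c("urine", "feces", "background", "miss"),
    gt = c("urine", "feces", "background")))
  class(cm) <- c("confusion_matrix", class(cm))
  cm["urine", "urine"] <- 9L
  cm["urine", "background"] <- 1L   # FP
  cm["miss", "urine"] <- 2L         # FN
  rep <- score_report(cm)
  u <- rep$scores[rep$scores$class == "urine", ]
  expect_equal(u$precision, 0.9)
  expect_equal(u$recall, 9 / 11)
  expect_equal(u$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))

  # all missed -> recall and F1 are 0, not NaN
  cm0 <- cm; cm0[, ] <- 0L; cm0["miss", "urine"] <- 3L
  rep0 <- score_report(cm0)
  expect_equal(rep0$scores$recall, c(0, 0))
  expect_equal(rep0$scores$f1, c(0, 0))
  expect_equal(rep0$mean_f1, 0)
})

test_that("matching agrees exactly with the brute-force reference", {
  n_checked <- 0
  for (seed in 1:200) {
    cfgx <- random_match_config(seed)
    m <- match_events(cfgx$gt, cfgx$det, fps = fps)
    cm <- build_confusion(m)
    ref <- ref_match(cfgx$gt, cfgx$det, fps = fps)
    expect_identical(m$gt$status, ref$gt_status)
    expect_identical(m$det$role, ref$det_role)
    expect_identical(unclass(cm)[, ], ref$cm[, ])

    # conservation: every GT event and detection accounted exactly once
    expect_true(all(m$gt$status %in% c("correct", "misclassified", "missed")))
    expect_true(all(m$det$role %in%
                      c("absorbed", "misclassification", "false_alarm",
                        "background")))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("matching is invariant under global translation and time shift", {
  # integer coordinates and a dyadic frame rate keep the arithmetic exact
  # even on the tolerance boundary
  set.seed(40)
  gt <- tibble::tibble(label = sample(c("urine", "feces"), 6, TRUE),
                       frame = sample(seq(0L, 800L, 8L), 6),
                       x = sample(0:60, 6), y = sample(0:60, 6))
  det <- tibble::tibble(det_id = 1:8,
                        label = sample(c("urine", "feces", "background"),
                                       8, TRUE),
                        time_s = sample(seq(0L, 800L, 8L), 8) / 8,
                        x = sample(0:60, 8), y = sample(0:60, 8))
  m1 <- match_events(gt, det, fps = 8)
  gt2 <- dplyr::mutate(gt, x = x + 13, y = y + 5, frame = frame + 256L)
  det2 <- dplyr::mutate(det, x = x + 13, y = y + 5, time_s = time_s + 32)
  m2 <- match_events(gt2, det2, fps = 8)
  expect_identical(m1$gt$status, m2$gt$status)
  expect_identical(m1$det$role, m2$det$role)
})

test_that("stratified reports skip classes with no ground truth", {
  gt <- tibble::tibble(label = rep("urine", 4),
                       frame = c(0L, 200L, 400L, 600L),
                       x = c(10, 50, 70, 110), y = 50)
  det <- tibble::tibble(det_id = 1:4, label = "urine",
                        time_s = gt$frame / fps, x = gt$x, y = gt$y)
  # single all-covering stratum equals the overall report
  all_sel <- list(everything = list(gt = rep(TRUE, 4), det = rep(TRUE, 4)))
  strat <- stratified_report(gt, det, fps = fps, strata = all_sel)
  expect_equal(strat$f1[strat$class == "urine"], 1)
  # feces has no ground truth anywhere -> NA, not 0
  expect_true(is.na(strat$f1[strat$class == "feces"]))

  # spatial thirds: events only in the outer thirds here
  ann <- toy_annotation(W = 120, H = 60, margin = 5)
  thirds <- strata_floor_thirds(gt, det, ann)
  rep3 <- stratified_report(gt, det, fps = fps, strata = thirds)
  mid_urine <- rep3[rep3$stratum == "third_2" & rep3$class == "urine", ]
  expect_equal(mid_urine$n_gt, 2L)  # x = 60, 70 fall in the middle third
  expect_equal(sum(rep3$n_gt[rep3$class == "urine"]), 4L)
})

test_that("stage strata partition ground truth by session stage", {
  s <- easy_session(101)
  det <- dplyr::mutate(s$detections, label = "urine")
  strata <- strata_stages(s$ground_truth, det, s$annotation, fps = fps)
  covered <- strata$habituation_start$gt | strata$habituation_end$gt |
    strata$trial$gt
  expect_true(all(covered))
})
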