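#' Matching tolerances
#'
#' A manually tagged deposition counts as correctly detected when an
#' automatic detection with the same label lies within `max_dist_px`
#' pixels and `max_dt_s` seconds (both inclusive). Spatial tolerance
#' absorbs the ambiguity of tagging large or smeared urine spots; temporal
#' tolerance absorbs delays caused by the mouse covering the deposit.
#'
#' @param max_dist_px Spatial tolerance in pixels (default 20, about
#'   2.9 cm at 0.02 cm^2 per pixel).
#' @param max_dt_s Temporal tolerance in seconds (default 15).
#' @return A list of class `match_config`.
#' @export
match_config <- function(max_dist_px = 20, max_dt_s = 15) {
  stopifnot_scalar_number(max_dist_px, "max_dist_px", positive = TRUE)
  stopifnot_scalar_number(max_dt_s, "max_dt_s", positive = TRUE)
  structure(list(max_dist_px = max_dist_px, max_dt_s = max_dt_s),
            class = "match_config")
}

#' Match ground-truth events to classified detections
#'
#' Applies the matching principles: (1) a ground-truth event is correct
#' when a same-label detection lies within the spatial and temporal
#' tolerance; (2) all same-label detections in that window are absorbed by
#' the event and are not false alarms; (3) when only different-label
#' detections exist in the window, the closest one (smallest spatial
#' distance, ties by smallest time difference, then lowest detection id)
#' is recorded as the misclassification of that event. Ground-truth events
#' are processed greedily in order of occurrence; a detection claimed by
#' one event is not available to later events. Detections never claimed by
#' any event are false alarms.
#'
#' @param gt Ground-truth tibble with columns `label`, `frame`, `x`, `y`
#'   (labels urine/feces, frames 0-based).
#' @param det Detections tibble with columns `det_id`, `label` (urine,
#'   feces or background), `time_s`, `x`, `y`.
#' @param cfg A [match_config()].
#' @param fps Frame rate used to convert ground-truth frames to seconds.
#' @return A list of class `match_result`: `gt` with added `status`
#'   (`correct`/`misclassified`/`missed`) and `pred_label`; `det` with
#'   added `role` (`absorbed`, `misclassification`, `false_alarm`, or
#'   `background` for unclaimed background-labeled detections).
#' @export
match_events <- function(gt, det, cfg = match_config(), fps = 8.66) {
  gt <- as_tibble(gt)
  det <- as_tibble(det)
  n_gt <- nrow(gt); n_det <- nrow(det)
  gt$status <- rep(NA_character_, n_gt)
  gt$pred_label <- rep(NA_character_, n_gt)
  det$role <- rep(NA_character_, n_det)
  gt_time <- gt$frame / fps
  order_gt <- order(gt$frame, seq_len(n_gt))
  available <- rep(TRUE, n_det)

  for (i in order_gt) {
    if (n_det == 0L) { gt$status[i] <- "missed"; next }
    d <- sqrt((det$x - gt$x[i])^2 + (det$y - gt$y[i])^2)
    dt <- abs(det$time_s - gt_time[i])
    win <- available & d <= cfg$max_dist_px & dt <= cfg$max_dt_s
    same <- win & det$label == gt$label[i]
    if (any(same)) {
      gt$status[i] <- "correct"
      gt$pred_label[i] <- gt$label[i]
      det$role[same] <- "absorbed"
      available[same] <- FALSE
    } else if (any(win)) {
      cand <- which(win)
      cand <- cand[order(d[cand], dt[cand], det$det_id[cand])]
      j <- cand[1]
      gt$status[i] <- "misclassified"
      gt$pred_label[i] <- det$label[j]
      det$role[j] <- "misclassification"
      available[j] <- FALSE
    } else {
      gt$status[i] <- "missed"
    }
  }
  unclaimed <- is.na(det$role)
  det$role[unclaimed & det$label != "background"] <- "false_alarm"
  det$role[unclaimed & det$label == "background"] <- "background"
  structure(list(gt = gt, det = det, cfg = cfg, fps = fps),
            class = "match_result")
}

#' Build the confusion matrix of a match result
#'
#' Rows are predicted categories (urine, feces, background, and `miss` for
#' events the preliminary detector never reached); columns are
#' ground-truth categories (urine, feces, and background for automatic
#' detections with no matching tag). The `background` column counts false
#' alarms by their predicted label; the `miss` row counts missed events by
#' their true label.
#'
#' @param match A `match_result` from [match_events()].
#' @return A `confusion_matrix`: a 4 x 3 integer matrix with dimnames
#'   `pred` x `gt`.
#' @export
build_confusion <- function(match) {
  preds <- c("urine", "feces", "background", "miss")
  gts <- c("urine", "feces", "background")
  cm <- matrix(0L, 4, 3, dimnames = list(pred = preds, gt = gts))
  gt <- match$gt
  for (i in seq_len(nrow(gt))) {
    if (gt$status[i] == "missed")
      cm["miss", gt$label[i]] <- cm["miss", gt$label[i]] + 1L
    else
      cm[gt$pred_label[i], gt$label[i]] <- cm[gt$pred_label[i], gt$label[i]] + 1L
  }
  det <- match$det
  fa <- det$role == "false_alarm"
  for (lab in c("urine", "feces"))
    cm[lab, "background"] <- cm[lab, "background"] + sum(fa & det$label == lab)
  cm["background", "background"] <-
    cm["background", "background"] + sum(det$role == "background")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Accuracy report from a confusion matrix
#'
#' For each deposit class: TP = correctly detected and classified events;
#' FP = false alarms with that predicted label plus other events
#' misclassified into it; FN = missed events plus events of that class
#' misclassified into anything else (including background). Precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean, all 0 when the
#' denominator is 0. The mean F1 is `(F1_urine + F1_feces) / 2`.
#'
#' @param cm A `confusion_matrix` from [build_confusion()].
#' @return A list of class `accuracy_report`: `scores` tibble (class,
#'   tp, fp, fn, precision, recall, f1), `mean_f1`, and the matrix.
#' @export
score_report <- function(cm) {
  classes <- c("urine", "feces")
  rows <- purrr::map(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[cl, colnames(cm) != cl])
    fn <- sum(cm[rownames(cm) != cl, cl])
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    tibble(class = cl, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1)
  })
  scores <- dplyr::bind_rows(rows)
  structure(list(scores = scores, mean_f1 = mean(scores$f1),
                 confusion = cm),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  print(x$scores)
  cat(sprintf("mean F1: %.3f\n", x$mean_f1))
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' Convenience wrapper: match, tally, score.
#'
#' @inheritParams match_events
#' @return An `accuracy_report`.
#' @export
evaluate_detections <- function(gt, det, cfg = match_config(), fps = 8.66) {
  score_report(build_confusion(match_events(gt, det, cfg, fps)))
}

#' Stratified accuracy reports
#'
#' Evaluates matching within subsets of the ground truth and detections —
#' e.g. stage windows, experiment type, subject sex, or equal-width thirds
#' of the arena floor. A class with no ground-truth events in a stratum is
#' reported as `NA` (its F1 is undefined there), not 0.
#'
#' @inheritParams match_events
#' @param strata Named list; each element is a list with logical vectors
#'   `gt` and `det` selecting the stratum's rows. See
#'   [strata_floor_thirds()] and [strata_stages()].
#' @return A tibble with one row per stratum and class: `stratum`,
#'   `class`, `n_gt`, `precision`, `recall`, `f1` (NA where undefined),
#'   plus `mean_f1` per stratum (NA unless both classes are defined).
#' @export
stratified_report <- function(gt, det, cfg = match_config(), fps = 8.66,
                              strata = list()) {
  out <- purrr::imap(strata, function(sel, name) {
    g <- gt[sel$gt, , drop = FALSE]
    d <- det[sel$det, , drop = FALSE]
    rep <- score_report(build_confusion(match_events(g, d, cfg, fps)))
    sc <- rep$scores
    sc$stratum <- name
    sc$n_gt <- purrr::map_int(sc$class, ~ sum(g$label == .x))
    sc$precision[sc$n_gt == 0] <- NA_real_
    sc$recall[sc$n_gt == 0] <- NA_real_
    sc$f1[sc$n_gt == 0] <- NA_real_
    sc[, c("stratum", "class", "n_gt", "precision", "recall", "f1")]
  })
  dplyr::bind_rows(out)
}

#' Stratum selectors
#'
#' `strata_stages()` splits by session stage (habituation start / end /
#' trial — the habituation halves split its interval in two);
#' `strata_floor_thirds()` splits the arena floor's bounding box into
#' three equal widths along its long axis.
#'
#' @param gt,det Tables as in [match_events()].
#' @param annotation An [arena_annotation()].
#' @param fps Frame rate.
#' @return A named list of strata for [stratified_report()].
#' @export
strata_stages <- function(gt, det, annotation, fps = 8.66) {
  hab <- annotation$habituation_interval
  mid <- floor((hab[1] + hab[2]) / 2)
  tri <- annotation$trial_interval
  gt_f <- gt$frame
  det_f <- round(det$time_s * fps)
  sel <- function(lo, hi) list(gt = gt_f >= lo & gt_f <= hi,
                               det = det_f >= lo & det_f <= hi)
  list(habituation_start = sel(hab[1], mid),
       habituation_end = sel(mid + 1, hab[2]),
       trial = sel(tri[1], tri[2]))
}

#' @rdname strata_stages
#' @export
strata_floor_thirds <- function(gt, det, annotation) {
  ax <- floor_long_axis(annotation)
  brk <- seq(ax$range[1], ax$range[2], length.out = 4)
  coord_gt <- if (ax$axis == "x") gt$x else gt$y
  coord_det <- if (ax$axis == "x") det$x else det$y
  cut3 <- function(v) pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L), 3L)
  g3 <- cut3(coord_gt); d3 <- cut3(coord_det)
  setNames(
    purrr::map(1:3, function(k) list(gt = g3 == k, det = d3 == k)),
    c("third_1", "third_2", "third_3"))
}
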