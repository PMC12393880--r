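#' Deposition events from classified detections
#'
#' Keeps detections classified as urine or feces and expresses them as
#' deposition events: stage, stage-relative time, position, area and arena
#' side.
#'
#' @param detections Classified detections (see [classify_detections()]);
#'   must have `stage`, `selected_frame`, `x`, `y`, `area_cm2`, `label`.
#' @param annotation An [arena_annotation()].
#' @param fps Frame rate.
#' @return A tibble with columns `label`, `stage`, `time_s` (seconds from
#'   the stage start), `x`, `y`, `area_cm2`, `side`.
#' @export
deposition_events <- function(detections, annotation, fps = 8.66) {
  det <- detections[detections$label %in% c("urine", "feces"), , drop = FALSE]
  stage_start <- ifelse(det$stage == "habituation",
                        annotation$habituation_interval[1],
                        annotation$trial_interval[1])
  tibble(label = det$label, stage = det$stage,
         time_s = (det$selected_frame - stage_start) / fps,
         x = det$x, y = det$y, area_cm2 = det$area_cm2,
         side = assign_side(det$x, det$y, annotation))
}

#' Per-minute deposition series
#'
#' Event counts and area sums in minute bins `[60k, 60(k+1))` seconds of
#' stage-relative time, per stage and label.
#'
#' @param events Events tibble from [deposition_events()].
#' @param stage_lengths_s Named vector of stage lengths in seconds, e.g.
#'   `c(habituation = 900, trial = 300)`; defines how many (possibly
#'   empty) minute bins each stage contributes.
#' @return A tibble `stage`, `label`, `minute` (1-based bin index),
#'   `rate` (events in the bin) and `area` (cm^2 deposited in the bin).
#' @export
per_minute_series <- function(events, stage_lengths_s) {
  grid <- purrr::imap(as.list(stage_lengths_s), function(len, stage) {
    tidyr::expand_grid(stage = stage, label = c("urine", "feces"),
                       minute = seq_len(max(1L, ceiling(len / 60))))
  })
  grid <- dplyr::bind_rows(grid)
  ev <- events
  ev$minute <- floor(ev$time_s / 60) + 1L
  agg <- ev |>
    dplyr::group_by(.data$stage, .data$label, .data$minute) |>
    dplyr::summarise(rate = dplyr::n(), area = sum(.data$area_cm2),
                     .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = c("stage", "label", "minute"))
  out$rate[is.na(out$rate)] <- 0
  out$area[is.na(out$area)] <- 0
  out
}

# minute windows of the stage summary, as [lo, hi) second intervals
stage_summary_windows <- function() {
  list(habituation_start = list(stage = "habituation", lo = 0, hi = 240),
       habituation_end = list(stage = "habituation", lo = 600, hi = 840),
       trial_min_1 = list(stage = "trial", lo = 0, hi = 60),
       trial_min_2_4 = list(stage = "trial", lo = 60, hi = 240),
       trial = list(stage = "trial", lo = 0, hi = 240))
}

#' Stage-window summary
#'
#' Mean deposition rate (events/min) and area rate (cm^2/min) over the
#' canonical comparison windows: habituation minutes 1-4 and 11-14, trial
#' minute 1, trial minutes 2-4 and trial minutes 1-4 (half-open second
#' intervals [0, 240), [600, 840), [0, 60), [60, 240), [0, 240)). The last
#' minute of each stage (habituation minute 15, trial minute 5) can be
#' excluded because the classifier needs a minute of video after each
#' deposition; the canonical windows never contain those minutes, so the
#' flag only affects events falling there. A subject is "active" for a
#' label when it has at least one event of that label anywhere in the
#' session.
#'
#' @param events Events tibble from [deposition_events()].
#' @param stage_lengths_s Named stage lengths in seconds; windows are
#'   truncated to the actual stage length and rates use the truncated
#'   duration.
#' @param exclude_last_minute Drop events in habituation minute 15 and
#'   trial minute 5 before summarising.
#' @return A list of class `stage_summary`: `windows` tibble (`window`,
#'   `label`, `n`, `minutes`, `rate_per_min`, `area_per_min`) and
#'   `active` tibble (`label`, `active`).
#' @export
stage_summary <- function(events,
                          stage_lengths_s = c(habituation = 900, trial = 300),
                          exclude_last_minute = TRUE) {
  ev <- events
  if (exclude_last_minute) {
    drop <- (ev$stage == "habituation" & ev$time_s >= 840 & ev$time_s < 900) |
      (ev$stage == "trial" & ev$time_s >= 240 & ev$time_s < 300)
    ev <- ev[!drop, , drop = FALSE]
  }
  rows <- purrr::imap(stage_summary_windows(), function(w, name) {
    len <- stage_lengths_s[[w$stage]] %||% 0
    hi <- min(w$hi, len)
    minutes <- max(hi - w$lo, 0) / 60
    purrr::map(c("urine", "feces"), function(lab) {
      inw <- ev$stage == w$stage & ev$label == lab &
        ev$time_s >= w$lo & ev$time_s < hi
      tibble(window = name, label = lab, n = sum(inw), minutes = minutes,
             rate_per_min = if (minutes > 0) sum(inw) / minutes else NA_real_,
             area_per_min = if (minutes > 0)
               sum(ev$area_cm2[inw]) / minutes else NA_real_)
    })
  })
  windows <- dplyr::bind_rows(purrr::flatten(rows))
  active <- tibble(label = c("urine", "feces"),
                   active = c(any(events$label == "urine"),
                              any(events$label == "feces")))
  structure(list(windows = windows, active = active), class = "stage_summary")
}

#' Arena-side attribution of deposition events
#'
#' Counts events per arena side and reports the fraction deposited on the
#' preferred-stimulus side.
#'
#' @param events Events tibble from [deposition_events()] (its `side`
#'   column is recomputed here from positions).
#' @param annotation An [arena_annotation()].
#' @return A list: `by_side` tibble (`label`, `side`, `n`),
#'   `preferred_fraction` tibble (`label`, `n_total`, `fraction`), where
#'   the fraction is `NA` when the session has no preferred side or no
#'   events of the label.
#' @export
side_attribution <- function(events, annotation) {
  side <- assign_side(events$x, events$y, annotation)
  by_side <- tibble(label = events$label, side = side) |>
    dplyr::count(.data$label, .data$side, name = "n")
  pref <- annotation$preferred_side
  frac <- purrr::map(c("urine", "feces"), function(lab) {
    n_tot <- sum(events$label == lab)
    f <- if (!is.na(pref) && n_tot > 0)
      sum(events$label == lab & side == pref) / n_tot else NA_real_
    tibble(label = lab, n_total = n_tot, fraction = f)
  })
  list(by_side = by_side, preferred_fraction = dplyr::bind_rows(frac))
}
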