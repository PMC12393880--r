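#' Session annotation
#'
#' Manual per-session inputs: the arena-floor polygon, the blackbody region
#' polygon, the habituation and trial frame intervals, and the mapping of
#' the two arena halves to stimulus labels. All coordinates are 0-based
#' pixels (x = column, y = row, origin top-left); frame intervals are closed
#' `[first, last]` in 0-based frames. The two stages must not overlap; the
#' frames between them (stimulus introduction, ~30 s) are excluded from all
#' analysis.
#'
#' @param floor_polygon Two-column matrix (or data frame) of `(x, y)` vertex
#'   coordinates of the arena floor, at least 3 vertices, simple
#'   (non-self-intersecting).
#' @param blackbody_polygon Same, for the blackbody region.
#' @param habituation_interval,trial_interval Closed frame intervals
#'   `c(first, last)`, habituation strictly before trial.
#' @param side_map Named character vector of length 2 mapping the two arena
#'   halves to stimulus labels, in increasing position along the floor
#'   bounding box's long axis, e.g. `c(left = "social", right = "object")`.
#'   The names are labels for the halves; the order defines the tie rule
#'   (midline points go to the first-listed side).
#' @param preferred_side Stimulus label of the preferred side, or `NA`.
#' @return An object of class `arena_annotation`.
#' @export
arena_annotation <- function(floor_polygon, blackbody_polygon,
                             habituation_interval, trial_interval,
                             side_map = c(left = "A", right = "B"),
                             preferred_side = NA_character_) {
  floor_polygon <- as_polygon(floor_polygon, "floor_polygon")
  blackbody_polygon <- as_polygon(blackbody_polygon, "blackbody_polygon")
  check_interval(habituation_interval, "habituation_interval")
  check_interval(trial_interval, "trial_interval")
  if (trial_interval[1] <= habituation_interval[2])
    abort("`trial_interval` must start after `habituation_interval` ends.")
  if (length(side_map) != 2L || is.null(names(side_map)) ||
      any(!nzchar(names(side_map))))
    abort("`side_map` must be a named character vector of length 2.")
  if (!is.na(preferred_side) && !preferred_side %in% unname(side_map))
    abort("`preferred_side` must be one of the side_map labels or NA.")
  structure(
    list(floor_polygon = floor_polygon,
         blackbody_polygon = blackbody_polygon,
         habituation_interval = as.integer(habituation_interval),
         trial_interval = as.integer(trial_interval),
         side_map = side_map,
         preferred_side = preferred_side),
    class = "arena_annotation")
}

as_polygon <- function(p, name) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    abort(sprintf("`%s` must have >= 3 (x, y) vertices.", name))
  if (!all(is.finite(p))) abort(sprintf("`%s` has non-finite vertices.", name))
  if (polygon_self_intersects(p))
    abort(sprintf("`%s` must be simple (non-self-intersecting).", name))
  colnames(p) <- c("x", "y")
  unname(p)
}

check_interval <- function(iv, name) {
  if (length(iv) != 2L || any(!is.finite(iv)) || iv[1] > iv[2] || any(iv < 0))
    abort(sprintf("`%s` must be a closed frame interval c(first, last), first <= last >= 0.", name))
}

# Segment-intersection test for polygon simplicity (proper crossings only;
# shared endpoints of adjacent edges are allowed).
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  for (i in seq_len(n - 2L)) {
    last_j <- if (i == 1L) n - 1L else n
    if (last_j < i + 2L) next
    for (j in seq(i + 2L, last_j)) {
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- cross(a, b, c); d2 <- cross(a, b, d)
      d3 <- cross(c, d, a); d4 <- cross(c, d, b)
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel `(x, y)` (0-based) is included iff its center lies inside the
#' polygon under the even-odd rule. Vertex order (clockwise or
#' counter-clockwise) does not matter.
#'
#' @param polygon Two-column matrix of `(x, y)` vertices.
#' @param height,width Output mask shape in pixels.
#' @return An `height x width` logical matrix.
#' @export
rasterize_polygon <- function(polygon, height, width) {
  polygon <- as_polygon(polygon, "polygon")
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  xs <- seq_len(width) - 1  # pixel-center x
  mask <- matrix(FALSE, height, width)
  for (yy in seq_len(height) - 1) {
    inside <- rep(FALSE, width)
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > yy) != (py[j] > yy)) {
        xint <- (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i]
        flip <- xs < xint
        inside <- xor(inside, flip)
      }
      j <- i
    }
    mask[yy + 1L, ] <- inside
  }
  mask
}

# Bounding box (0-based, from vertex coordinates) and midline of the floor.
floor_long_axis <- function(annotation) {
  p <- annotation$floor_polygon
  xr <- range(p[, 1]); yr <- range(p[, 2])
  if (diff(xr) >= diff(yr)) list(axis = "x", mid = mean(xr), range = xr)
  else list(axis = "y", mid = mean(yr), range = yr)
}

#' Assign an arena side to a point
#'
#' The arena is split by the midline perpendicular to the floor bounding
#' box's long axis (the stimulus chambers sit at opposite ends of the long
#' axis). Points exactly on the midline go to the first-listed side of
#' `side_map`.
#'
#' @param x,y Point coordinates (0-based pixels); vectors are accepted.
#' @param annotation An [arena_annotation()].
#' @return Character vector of stimulus labels.
#' @export
assign_side <- function(x, y, annotation) {
  ax <- floor_long_axis(annotation)
  coord <- if (ax$axis == "x") x else y
  ifelse(coord <= ax$mid, unname(annotation$side_map[1]),
         unname(annotation$side_map[2]))
}

#' Read and write annotation JSON
#'
#' The annotation is stored as a single JSON document with a fixed key
#' order, so saving a loaded annotation reproduces the file byte for byte.
#'
#' @param annotation An [arena_annotation()].
#' @param path JSON file path.
#' @param n_frames Optional video length; when supplied, intervals are
#'   checked against it.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "arena_annotation"))
  doc <- list(
    floor_polygon = unname(apply(annotation$floor_polygon, 1, as.numeric,
                                 simplify = FALSE)),
    blackbody_polygon = unname(apply(annotation$blackbody_polygon, 1,
                                     as.numeric, simplify = FALSE)),
    habituation_interval = annotation$habituation_interval,
    trial_interval = annotation$trial_interval,
    side_map = as.list(annotation$side_map),
    preferred_side = if (is.na(annotation$preferred_side)) NULL
                     else annotation$preferred_side)
  write_json_canonical(doc, path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, n_frames = NULL) {
  doc <- read_json(path)
  need <- c("floor_polygon", "blackbody_polygon", "habituation_interval",
            "trial_interval", "side_map")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    abort(sprintf("Annotation JSON missing fields: %s",
                  paste(missing, collapse = ", ")))
  to_mat <- function(v) {
    if (is.list(v)) do.call(rbind, v) else v
  }
  ann <- arena_annotation(
    floor_polygon = to_mat(doc$floor_polygon),
    blackbody_polygon = to_mat(doc$blackbody_polygon),
    habituation_interval = doc$habituation_interval,
    trial_interval = doc$trial_interval,
    side_map = unlist(doc$side_map),
    preferred_side = doc$preferred_side %||% NA_character_)
  if (!is.null(n_frames) && ann$trial_interval[2] >= n_frames)
    abort("Annotation intervals exceed the video length.")
  ann
}

#' Read and write ground-truth event tables
#'
#' Manually tagged deposition events: one row per single-click tag with the
#' event label (`urine` or `feces`), the 0-based frame of first clear
#' visibility and the click position in 0-based pixels.
#'
#' @param events A data frame with columns `label`, `frame`, `x`, `y`.
#' @param path CSV path.
#' @return A tibble with columns `label`, `frame`, `x`, `y`.
#' @export
write_ground_truth <- function(events, path) {
  events <- validate_ground_truth(events)
  write_csv_stable(events[, c("label", "frame", "x", "y")], path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), frame = readr::col_integer(),
    x = readr::col_double(), y = readr::col_double()))
  validate_ground_truth(ev)
}

validate_ground_truth <- function(events) {
  events <- as_tibble(events)
  need <- c("label", "frame", "x", "y")
  if (!all(need %in% names(events)))
    abort("Ground truth needs columns label, frame, x, y.")
  if (!all(events$label %in% c("urine", "feces")))
    abort("Ground-truth labels must be 'urine' or 'feces'.")
  events$frame <- as.integer(events$frame)
  events
}

#' Stage of a frame index
#'
#' Maps 0-based frame indices to `"habituation"`, `"trial"` or `NA` (the
#' stimulus-introduction gap or outside both stages).
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param annotation An [arena_annotation()].
#' @return Character vector.
#' @export
frame_stage <- function(frame, annotation) {
  dplyr::case_when(
    frame >= annotation$habituation_interval[1] &
      frame <= annotation$habituation_interval[2] ~ "habituation",
    frame >= annotation$trial_interval[1] &
      frame <= annotation$trial_interval[2] ~ "trial",
    TRUE ~ NA_character_)
}
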