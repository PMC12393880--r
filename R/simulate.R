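#' Synthetic thermal-session configuration
#'
#' Describes a simulated session: a warm mouse performing a reflecting
#' random walk on a cooler arena floor, scheduled deposition events that
#' appear at body temperature and decay exponentially to slightly below
#' floor temperature, Gaussian sensor noise, a fixed-pattern non-uniformity
#' image, global sensor drift and a constant-temperature blackbody patch.
#' The rendered video is uncalibrated (non-uniformity and drift applied);
#' the emitted [calibration_bundle()] recovers the clean scene.
#'
#' @param width,height Frame size in pixels (default 384 x 288, the target
#'   camera's resolution).
#' @param fps Frame rate (default 8.66).
#' @param habituation_s,trial_s,gap_s Stage durations in seconds. The gap
#'   emulates stimulus introduction and is excluded from analysis.
#' @param floor_margin Pixels between the frame border and the arena floor.
#' @param floor_temp Mean floor temperature, deg C.
#' @param floor_sigma Spatial standard deviation of the static floor
#'   texture, deg C.
#' @param ambient_temp Temperature outside the arena floor.
#' @param mouse_temp Mouse surface temperature (about 35 deg C).
#' @param mouse_radius Mouse disk radius in pixels (soft-edged).
#' @param step_sigma Random-walk step standard deviation, px/frame.
#' @param dwell_prob Per-frame probability of pausing (dwelling).
#' @param events Either `NULL` (a schedule is sampled from the event preset
#'   fields below) or a data frame with columns `stage`, `time_s`, `x`,
#'   `y`, `label`, `radius`, `peak_dT`, `tau_s`, `dark_offset`.
#' @param n_urine,n_feces Number of events per session when sampling a
#'   schedule (split across stages).
#' @param urine_radius,feces_radius Radius ranges (px) for sampled events.
#' @param urine_tau,feces_tau Cooldown time-constant ranges (s). Feces and
#'   small urine cool in tens of seconds; large urine cools more slowly.
#'   Note that a single-exponential deposit is only detectable by the
#'   cooldown-fraction test when `tau_s < horizon / log(2)` (about 57.7 s
#'   for the default 40 s horizon).
#' @param urine_peak,feces_peak Peak temperature-rise ranges (deg C).
#' @param dark_offset Below-floor asymptote of cooled deposits (deg C).
#' @param event_time_range Allowed event times within each stage (s).
#' @param min_mouse_dist Minimum distance (px) between an event site and
#'   the mouse center during the deposition window (0 disables; used by the
#'   occlusion preset).
#' @param min_event_sep Minimum distance between event sites (px).
#' @param noise_sigma Per-pixel Gaussian sensor noise, deg C.
#' @param nuc_amplitude Standard deviation of the fixed-pattern
#'   non-uniformity image, deg C.
#' @param drift_amplitude,drift_period_s Global sinusoidal sensor drift.
#' @param blackbody_temp Blackbody setpoint, deg C.
#' @param seed Integer seed; a fixed seed makes the rendered session
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(width = 384, height = 288, fps = 8.66,
                       habituation_s = 120, trial_s = 120, gap_s = 3,
                       floor_margin = 24,
                       floor_temp = 25, floor_sigma = 0.25,
                       ambient_temp = 23,
                       mouse_temp = 35, mouse_radius = 12,
                       step_sigma = 2.5, dwell_prob = 0.05,
                       events = NULL,
                       n_urine = 5, n_feces = 5,
                       urine_radius = c(7, 10), feces_radius = c(1.5, 2.5),
                       urine_tau = c(40, 52), feces_tau = c(30, 45),
                       urine_peak = c(8, 11), feces_peak = c(7, 10),
                       dark_offset = 0.5,
                       event_time_range = c(8, 70),
                       min_mouse_dist = 25, min_event_sep = 40,
                       noise_sigma = 0.05, nuc_amplitude = 0.3,
                       drift_amplitude = 0.4, drift_period_s = 180,
                       blackbody_temp = 37, seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(events)) cfg$events <- as_tibble(events)
  stopifnot(width > 40, height > 40, fps > 0, habituation_s > 0, trial_s > 0)
  structure(cfg, class = "sim_config")
}

#' Session presets
#'
#' Loads one of the shipped preset configurations (`easy`, `occlusion`,
#' `dense`) from the package's `presets/` directory and merges overrides.
#' `easy` is a desk-scale session (160 x 120 px, two 2-minute stages, 5
#' urine + 5 feces, low noise, mouse kept away from deposit sites);
#' `occlusion` lets the mouse linger on deposit sites; `dense` schedules
#' many events.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("easy", "occlusion", "dense"), seed = 1L, ...) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".yaml"), package = "thermark")
  if (path == "") abort(sprintf("Preset '%s' not found.", name))
  vals <- yaml::read_yaml(path)
  args <- modifyList(vals, list(seed = seed, ...))
  do.call(sim_config, args)
}

sim_floor_polygon <- function(config) {
  m <- config$floor_margin
  w <- config$width; h <- config$height
  # vertices at pixel-center corners; pixels m..(w-1-m) are inside
  rbind(c(m - 0.5, m - 0.5), c(w - m - 0.5, m - 0.5),
        c(w - m - 0.5, h - m - 0.5), c(m - 0.5, h - m - 0.5))
}

sim_blackbody_polygon <- function(config) {
  # small patch in the top-left corner, outside the floor
  s <- max(4, round(min(config$floor_margin - 2, 10)))
  rbind(c(1.5, 1.5), c(1.5 + s, 1.5), c(1.5 + s, 1.5 + s), c(1.5, 1.5 + s))
}

sim_stage_frames <- function(config) {
  n_hab <- as.integer(round(config$habituation_s * config$fps))
  n_gap <- as.integer(round(config$gap_s * config$fps))
  n_trial <- as.integer(round(config$trial_s * config$fps))
  list(hab = c(0L, n_hab - 1L),
       trial = c(n_hab + n_gap, n_hab + n_gap + n_trial - 1L),
       n_total = n_hab + n_gap + n_trial)
}

#' Simulate a mouse trajectory
#'
#' Reflecting Gaussian random walk inside the arena floor (kept
#' `mouse_radius` away from the floor edge), with optional per-frame dwell
#' pauses. Uses the current RNG state; callers seed beforehand.
#'
#' @param config A [sim_config()].
#' @param n Number of frames (defaults to the whole session).
#' @return An `n x 2` matrix of `(x, y)` mouse-center coordinates.
#' @export
simulate_trajectory <- function(config, n = NULL) {
  st <- sim_stage_frames(config)
  if (is.null(n)) n <- st$n_total
  m <- config$floor_margin + config$mouse_radius
  lo <- c(m, m)
  hi <- c(config$width - 1 - m, config$height - 1 - m)
  pos <- matrix(0, n, 2)
  cur <- lo + runif(2) * (hi - lo)
  reflect <- function(v, lo, hi) {
    # fold the coordinate back into [lo, hi]
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  for (i in seq_len(n)) {
    if (config$step_sigma > 0 && runif(1) >= config$dwell_prob) {
      cur <- cur + rnorm(2, 0, config$step_sigma)
      cur[1] <- reflect(cur[1], lo[1], hi[1])
      cur[2] <- reflect(cur[2], lo[2], hi[2])
    }
    pos[i, ] <- cur
  }
  pos
}

# Sample an event schedule compatible with the trajectory: events inside
# the floor (with margin), separated from each other, and (optionally) away
# from the mouse center around deposition time.
sample_event_schedule <- function(config, trajectory) {
  st <- sim_stage_frames(config)
  stage_len <- c(habituation = config$habituation_s, trial = config$trial_s)
  specs <- list()
  split2 <- function(k) c(ceiling(k / 2), floor(k / 2))
  nu <- split2(config$n_urine); nf <- split2(config$n_feces)
  mk <- function(label, k, stage) {
    if (k <= 0) return(NULL)
    tibble(label = label, stage = stage, idx = seq_len(k))
  }
  plan <- dplyr::bind_rows(
    mk("urine", nu[1], "habituation"), mk("urine", nu[2], "trial"),
    mk("feces", nf[1], "habituation"), mk("feces", nf[2], "trial"))
  if (is.null(plan) || nrow(plan) == 0L) return(tibble())
  placed <- NULL
  rows <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    lab <- plan$label[r]; stage <- plan$stage[r]
    rad_rng <- if (lab == "urine") config$urine_radius else config$feces_radius
    tau_rng <- if (lab == "urine") config$urine_tau else config$feces_tau
    pk_rng <- if (lab == "urine") config$urine_peak else config$feces_peak
    # keep 50 s of stage after each event so the cooldown window and the
    # classifier's forward patches are not truncated
    t_hi <- min(config$event_time_range[2], stage_len[[stage]] - 50)
    t_lo <- config$event_time_range[1]
    if (t_hi < t_lo)
      abort(sprintf(
        "Stage '%s' (%g s) is too short for events in [%g, %g] s.",
        stage, stage_len[[stage]], config$event_time_range[1],
        config$event_time_range[2]))
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      radius <- runif(1, rad_rng[1], rad_rng[2])
      t0 <- runif(1, t_lo, t_hi)
      marg <- config$floor_margin + radius + 8
      x <- runif(1, marg, config$width - 1 - marg)
      y <- runif(1, marg, config$height - 1 - marg)
      if (!is.null(placed)) {
        same_stage <- placed[placed$stage == stage, , drop = FALSE]
        if (nrow(same_stage) > 0 &&
            any(sqrt((same_stage$x - x)^2 + (same_stage$y - y)^2) <
                  config$min_event_sep))
          next
      }
      if (config$min_mouse_dist > 0) {
        stage0 <- if (stage == "habituation") st$hab[1] else st$trial[1]
        f0 <- stage0 + round(t0 * config$fps)
        win <- seq(max(1, f0 - round(1 * config$fps)),
                   min(nrow(trajectory), f0 + round(15 * config$fps)))
        d <- sqrt((trajectory[win, 1] - x)^2 + (trajectory[win, 2] - y)^2)
        if (min(d) < config$min_mouse_dist) next
      }
      ok <- TRUE
      break
    }
    if (!ok) abort("Could not place a simulated event after 1000 attempts.")
    row <- tibble(stage = stage, time_s = t0, x = x, y = y, label = lab,
                  radius = radius, peak_dT = runif(1, pk_rng[1], pk_rng[2]),
                  tau_s = runif(1, tau_rng[1], tau_rng[2]),
                  dark_offset = config$dark_offset)
    placed <- dplyr::bind_rows(placed, row)
    rows[[r]] <- row
  }
  dplyr::bind_rows(rows)
}

# Soft-edged disk weights for pixels in a bounding box around (cx, cy).
# `center_peak > 0` makes the profile mildly center-peaked (deposits are
# hottest at the center; thin edges cool faster), which is also what makes
# the peak-intensity pixel a meaningful localizer.
# Returns list(rows, cols, w) with w in [0, 1].
soft_disk <- function(cx, cy, radius, H, W, taper = 1.2, center_peak = 0) {
  r_out <- radius + 3 * taper
  xs <- max(0, floor(cx - r_out)):min(W - 1, ceiling(cx + r_out))
  ys <- max(0, floor(cy - r_out)):min(H - 1, ceiling(cy + r_out))
  if (length(xs) == 0L || length(ys) == 0L)
    return(list(rows = integer(), cols = integer(), w = numeric()))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  w <- ifelse(d <= radius, 1, exp(-((d - radius) / taper)^2))
  if (center_peak > 0)
    w <- w * (1 - center_peak * pmin(d / max(radius, 1), 1)^2)
  keep <- w > 0.01
  idx <- which(keep, arr.ind = TRUE)
  list(rows = ys[idx[, 1]] + 1L, cols = xs[idx[, 2]] + 1L, w = w[keep])
}

#' Render a synthetic session
#'
#' Renders the full thermal video for a [sim_config()]: static floor field,
#' soft-edged mouse disk following a random walk, scheduled deposits that
#' rise by `peak_dT` at deposition and decay exponentially (time constant
#' `tau_s`) towards `dark_offset` below the local floor, Gaussian sensor
#' noise, a fixed non-uniformity pattern, global sinusoidal drift, and a
#' blackbody patch at the setpoint. Ground truth and a session annotation
#' are emitted alongside.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_output` with fields `video` (uncalibrated
#'   [thermal_video()]), `calibration` ([calibration_bundle()]),
#'   `annotation` ([arena_annotation()]), `ground_truth` (tibble `label`,
#'   `frame`, `x`, `y` — 0-based absolute frames), `events` (the full
#'   schedule), `trajectory`, and `clean` (the noiseless, drift-free video,
#'   for calibration checks).
#' @export
render_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  H <- config$height; W <- config$width
  st <- sim_stage_frames(config)
  n <- st$n_total
  fps <- config$fps

  floor_poly <- sim_floor_polygon(config)
  bb_poly <- sim_blackbody_polygon(config)
  floor_mask <- rasterize_polygon(floor_poly, H, W)
  bb_mask <- rasterize_polygon(bb_poly, H, W)

  # static scene: ambient, floor field with smooth texture, blackbody patch
  base <- matrix(config$ambient_temp, H, W)
  texture <- matrix(rnorm(H * W, 0, config$floor_sigma), H, W)
  texture <- simple_blur(texture, 2)
  base[floor_mask] <- config$floor_temp + texture[floor_mask]
  base[bb_mask] <- config$blackbody_temp

  nuc <- matrix(rnorm(H * W, 0, config$nuc_amplitude), H, W)
  nuc <- nuc - mean(nuc)

  trajectory <- simulate_trajectory(config, n)
  events <- config$events
  if (is.null(events)) events <- sample_event_schedule(config, trajectory)
  if (nrow(events) > 0) {
    stage0 <- ifelse(events$stage == "habituation", st$hab[1], st$trial[1])
    events$frame <- as.integer(stage0 + round(events$time_s * fps))
    ev_disks <- purrr::pmap(events, function(x, y, radius, ...)
      soft_disk(x, y, radius, H, W, center_peak = 0.3))
    ev_lin <- purrr::map(ev_disks, function(d) cbind((d$cols - 1L) * H + d$rows, d$w))
  }

  # mouse disk template at integer offsets, reused every frame
  mouse_tpl <- local({
    R <- ceiling(config$mouse_radius + 3 * 1.2)
    xs <- -R:R; ys <- -R:R
    dmat <- sqrt(outer(ys^2, xs^2, "+"))
    w <- ifelse(dmat <= config$mouse_radius, 1,
                exp(-((dmat - config$mouse_radius) / 1.2)^2))
    keep <- which(w > 0.01, arr.ind = TRUE)
    dy <- ys[keep[, 1]]; dx <- xs[keep[, 2]]
    list(dy = dy, dx = dx, w = w[w > 0.01],
         inb = function(cx, cy)
           cx + dx >= 0 & cx + dx < W & cy + dy >= 0 & cy + dy < H)
  })

  clean <- array(0, dim = c(H, W, n))
  noisy <- array(0, dim = c(H, W, n))
  drift <- config$drift_amplitude * sin(2 * pi * (seq_len(n) - 1) /
                                          (config$drift_period_s * fps))
  nucv <- as.vector(nuc)
  for (i in seq_len(n)) {
    fr <- base
    if (nrow(events) > 0) {
      for (e in seq_len(nrow(events))) {
        u <- (i - 1L - events$frame[e]) / fps
        if (u < 0) next
        decay <- exp(-u / events$tau_s[e])
        delta <- events$peak_dT[e] * decay -
          events$dark_offset[e] * (1 - decay)
        lin <- ev_lin[[e]]
        fr[lin[, 1]] <- fr[lin[, 1]] + delta * lin[, 2]
      }
    }
    cx <- round(trajectory[i, 1]); cy <- round(trajectory[i, 2])
    lin <- (cx + mouse_tpl$dx) * H + (cy + mouse_tpl$dy) + 1L
    inb <- mouse_tpl$inb(cx, cy)
    lin <- lin[inb]; mw <- mouse_tpl$w[inb]
    fr[lin] <- fr[lin] * (1 - mw) + config$mouse_temp * mw
    clean[, , i] <- fr
    noisy[, , i] <- fr + rnorm(H * W, 0, config$noise_sigma) + drift[i] + nucv
  }

  hab_iv <- st$hab
  trial_iv <- st$trial
  annotation <- arena_annotation(
    floor_polygon = floor_poly, blackbody_polygon = bb_poly,
    habituation_interval = hab_iv, trial_interval = trial_iv,
    side_map = c(left = "social", right = "object"),
    preferred_side = "social")

  gt <- if (nrow(events) > 0)
    tibble(label = events$label, frame = events$frame,
           x = round(events$x), y = round(events$y))
  else tibble(label = character(), frame = integer(), x = double(), y = double())

  as_video <- function(arr) structure(  # finite by construction
    list(frames = arr, fps = fps, timestamps = (seq_len(n) - 1) / fps,
         height = H, width = W), class = "thermal_video")
  structure(
    list(video = as_video(noisy),
         clean = as_video(clean),
         calibration = calibration_bundle(nuc, bb_mask, config$blackbody_temp),
         annotation = annotation,
         ground_truth = gt,
         events = events,
         trajectory = trajectory,
         config = config),
    class = "sim_output")
}

# Box blur with radius r (reflecting edges); keeps the texture smooth
# enough that the detector's per-pixel background stays meaningful.
simple_blur <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, H, W)
  cnt <- 2 * r + 1
  for (dy in -r:r) out <- out + m[idx(seq_len(H) + dy, H), ]
  out <- out / cnt
  acc <- matrix(0, H, W)
  for (dx in -r:r) acc <- acc + out[, idx(seq_len(W) + dx, W)]
  acc / cnt
}

#' Write a simulated session to disk
#'
#' Emits the standard artifacts of a session under `dir`: the thermal
#' container (`session.tif` + sidecar), the calibration bundle, the
#' annotation JSON and the ground-truth CSV.
#'
#' @param sim A `sim_output` from [render_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_thermal_video(sim$video, file.path(dir, "session"))
  write_calibration(sim$calibration, file.path(dir, "session"))
  write_annotation(sim$annotation, file.path(dir, "annotation.json"))
  write_ground_truth(sim$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
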