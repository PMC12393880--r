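test_that("trajectories stay on the floor and are seed-deterministic", {
  cfg <- sim_preset("easy", seed = 3)
  set.seed(1)
  tr <- simulate_trajectory(cfg, n = 10000)
  m <- cfg$floor_margin + cfg$mouse_radius
  expect_true(all(tr[, 1] >= m & tr[, 1] <= cfg$width - 1 - m))
  expect_true(all(tr[, 2] >= m & tr[, 2] <= cfg$height - 1 - m))

  # zero step size -> stationary
  cfg0 <- sim_preset("easy", seed = 3, step_sigma = 0)
  set.seed(2)
  tr0 <- simulate_trajectory(cfg0, n = 50)
  expect_true(all(tr0[, 1] == tr0[1, 1] & tr0[, 2] == tr0[1, 2]))

  set.seed(7); a <- simulate_trajectory(cfg, n = 500)
  set.seed(7); b <- simulate_trajectory(cfg, n = 500)
  expect_identical(a, b)
})

test_that("a session with no events, noise or motion is static", {
  cfg <- sim_config(width = 96, height = 80, habituation_s = 25, trial_s = 25,
                    gap_s = 1, floor_margin = 10, mouse_radius = 6,
                    n_urine = 0, n_feces = 0, step_sigma = 0, dwell_prob = 0,
                    noise_sigma = 0, nuc_amplitude = 0, drift_amplitude = 0,
                    seed = 5)
  sim <- render_session(cfg)
  fr1 <- sim$video$frames[, , 1]
  for (i in c(2, 100, n_frames(sim$video)))
    expect_identical(sim$video$frames[, , i], fr1)
})

test_that("deposits follow the exponential cooldown toward the dark offset", {
  tau <- 45; peak <- 10; dark <- 0.5
  events <- tibble::tibble(stage = "habituation", time_s = 10, x = 48, y = 40,
                           label = "urine", radius = 4, peak_dT = peak,
                           tau_s = tau, dark_offset = dark)
  cfg <- sim_config(width = 96, height = 80, habituation_s = 80, trial_s = 25,
                    gap_s = 1, floor_margin = 10, mouse_radius = 6,
                    events = events, step_sigma = 0, dwell_prob = 0,
                    noise_sigma = 0, nuc_amplitude = 0, drift_amplitude = 0,
                    seed = 6)
  sim <- render_session(cfg)
  fps <- cfg$fps
  f0 <- sim$ground_truth$frame[1]
  px <- sim$clean$frames[41, 49, ]  # event center (y+1, x+1)
  base <- px[f0]                    # pre-event floor value at that pixel
  # at t0 the pixel rises by the full peak
  expect_equal(px[f0 + 1] - base, peak, tolerance = 1e-9)
  # after one time constant it has decayed by 1 - e^-1 of the way to the
  # asymptote (base - dark)
  k_tau <- f0 + round(tau * fps)
  u <- (k_tau - f0) / fps
  expected <- base + (peak + dark) * exp(-u / tau) - dark
  expect_equal(px[k_tau + 1], expected, tolerance = 1e-9)
})

test_that("preset deposits satisfy the detector predicates on the clean curves", {
  horizon <- 40
  check_preset <- function(radius_rng, tau_rng, peak_rng, frac_ok) {
    # worst case within the preset ranges
    peak <- min(peak_rng); tau <- max(tau_rng); dark <- 0.5
    cd <- (peak + dark) * (1 - exp(-horizon / tau))
    d <- peak
    expect_gt(d, 1.6)
    expect_gt(cd, 1.1)
    if (frac_ok) expect_gt(cd, 0.5 * d)
  }
  cfg <- sim_preset("easy", seed = 1)
  check_preset(cfg$feces_radius, cfg$feces_tau, cfg$feces_peak, TRUE)
  check_preset(cfg$urine_radius, cfg$urine_tau, cfg$urine_peak, TRUE)
  # a slow large-urine deposit (tau up to 4 min) still exceeds the absolute
  # thresholds even though the fractional cooldown test needs tau below
  # horizon / ln 2
  check_preset(c(8, 10), c(180, 240), c(8, 11), FALSE)
})

test_that("rendered sessions are byte-identical under a fixed seed", {
  cfg <- sim_preset("easy", seed = 9, habituation_s = 60, trial_s = 60,
                    n_urine = 1, n_feces = 1)
  s1 <- render_session(cfg)
  s2 <- render_session(cfg)
  expect_identical(s1$video$frames, s2$video$frames)
  expect_identical(s1$ground_truth, s2$ground_truth)

  dir <- withr::local_tempdir()
  write_session(s1, file.path(dir, "a"))
  write_session(s2, file.path(dir, "b"))
  fa <- file.path(dir, "a", "session.tif"); fb <- file.path(dir, "b", "session.tif")
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("calibration inverts the simulated sensor model up to noise", {
  cfg <- sim_preset("easy", seed = 10, habituation_s = 60, trial_s = 60)
  sim <- render_session(cfg)
  cal <- apply_calibration(sim$video, sim$calibration)
  resid <- cal$frames - sim$clean$frames
  expect_lt(sqrt(mean(resid^2)), 1.2 * cfg$noise_sigma)
  expect_lt(max(abs(resid)), 6 * cfg$noise_sigma)
})

test_that("ground truth and annotation match the schedule", {
  s <- easy_session(102)
  gt <- s$ground_truth
  ann <- s$annotation
  stage <- frame_stage(gt$frame, ann)
  expect_false(any(is.na(stage)))
  fl <- rasterize_polygon(ann$floor_polygon, 120, 160)
  for (i in seq_len(nrow(gt)))
    expect_true(fl[gt$y[i] + 1, gt$x[i] + 1])
})
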