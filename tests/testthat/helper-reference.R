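# Independent brute-force reference implementations used as oracles.
# Deliberately naive: full recomputation per frame, no incremental buffers,
# no code shared with the package internals.

ref_disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

ref_dilate <- function(mask, r) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  off <- ref_disk_offsets(r)
  for (k in seq_len(nrow(off))) {
    dy <- off$dy[k]; dx <- off$dx[k]
    ys <- seq_len(H); xs <- seq_len(W)
    ys_src <- ys - dy; xs_src <- xs - dx
    ok_y <- ys_src >= 1 & ys_src <= H
    ok_x <- xs_src >= 1 & xs_src <= W
    out[ys[ok_y], xs[ok_x]] <-
      out[ys[ok_y], xs[ok_x]] | mask[ys_src[ok_y], xs_src[ok_x]]
  }
  out
}

ref_erode <- function(mask, r) {
  # out-of-image counts as foreground
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(TRUE, H + 2 * r, W + 2 * r)
  padded[r + seq_len(H), r + seq_len(W)] <- mask
  out <- matrix(TRUE, H, W)
  off <- ref_disk_offsets(r)
  for (k in seq_len(nrow(off)))
    out <- out & padded[r + seq_len(H) + off$dy[k],
                        r + seq_len(W) + off$dx[k]]
  out
}

# 8-connected labels in column-major raster order, BFS flood fill
ref_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- nxt
          queue[[length(queue) + 1L]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

ref_lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

# Full naive reference of the detector stage. Returns per-frame
# intermediates and the finalized detections.
ref_run_stage <- function(video, floor_mask, params = detector_params()) {
  n <- n_frames(video); fps <- video$fps
  H <- video$height; W <- video$width
  FR <- function(i) video$frames[, , i + 1]  # 0-based
  k_init <- round(params$bg_init_s * fps)
  B0 <- FR(0)
  for (i in seq_len(k_init - 1)) B0 <- pmin(B0, FR(i))
  lag_lo <- round(params$bg_window_s[1] * fps) + 1
  lag_hi <- round(params$bg_window_s[2] * fps) + 1
  horizon <- round(params$cooldown_horizon_s * fps)

  Ns <- vector("list", n)
  out <- list(M = vector("list", n), N = vector("list", n),
              B = vector("list", n), T_floor = numeric(n),
              D = vector("list", n), CD = vector("list", n),
              BM = vector("list", n))
  M_prev <- matrix(FALSE, H, W)
  B_prev <- B0
  tracks <- list()
  next_id <- 1L

  for (i in 0:(n - 1)) {
    Fi <- FR(i)
    warm <- (Fi - B_prev) > params$mouse_threshold
    dil <- ref_dilate(warm, params$mouse_dilate_radius)
    lab <- ref_label8(dil)
    M <- matrix(FALSE, H, W)
    if (max(lab) > 0) {
      ov <- sapply(seq_len(max(lab)), function(c) sum(floor_mask & lab == c))
      M <- lab == which.max(ov)
    }
    Nprev <- if (i == 0) B0 else Ns[[i]]
    Ni <- ifelse(M, Nprev, Fi)
    Ns[[i + 1]] <- Ni
    B <- NULL
    for (lag in lag_lo:lag_hi) {
      j <- i - lag
      Nj <- if (j < 0) B0 else Ns[[j + 1]]
      B <- if (is.null(B)) Nj else pmin(B, Nj)
    }
    elig <- floor_mask & !M & !M_prev
    Tfl <- ref_lower_median(B[elig])
    D <- Fi - pmax(Tfl, B)
    lastj <- min(n - 1, i + horizon)
    fut <- FR(i)
    for (j in i:lastj) fut <- pmin(fut, FR(j))
    CD <- Fi - fut
    BM <- (D > params$dT_threshold) & !M & !M_prev &
      (CD > params$cooldown_min_C) & (CD > params$cooldown_frac * D)

    # refinement
    cands <- list()
    if (any(BM)) {
      closed <- ref_erode(ref_dilate(BM, params$close_radius),
                          params$close_radius)
      blab <- ref_label8(closed)
      near <- ref_dilate(M | M_prev, 1)
      if (max(blab) > 0) for (c in seq_len(max(blab))) {
        px <- which(blab == c)
        if (length(px) < params$min_blob_px ||
            length(px) > params$max_blob_px) next
        if (any(!floor_mask[px]) || any(near[px])) next
        vals <- D[px]
        mx <- max(vals)
        ties <- px[vals == mx]
        yx <- arrayInd(ties, c(H, W))
        rep_px <- ties[order(yx[, 1], yx[, 2])][1]
        cands[[length(cands) + 1L]] <- list(px = px, peak = mx, rep_px = rep_px)
      }
    }
    # association
    for (cand in cands) {
      qual <- integer(0)
      for (t in seq_along(tracks)) {
        tr <- tracks[[t]]
        if ((i - tr$last_frame) / fps > params$assoc_max_gap_s) next
        if (length(intersect(cand$px, tr$union_px)) > 0) qual <- c(qual, t)
      }
      if (length(qual) == 0) {
        tracks[[length(tracks) + 1L]] <- list(
          id = next_id, first_frame = i, last_frame = i,
          union_px = cand$px,
          entries = list(list(frame = i, peak = cand$peak,
                              rep_px = cand$rep_px)))
        next_id <- next_id + 1L
      } else {
        firsts <- sapply(qual, function(t) tracks[[t]]$first_frame)
        ids <- sapply(qual, function(t) tracks[[t]]$id)
        t <- qual[order(firsts, ids)][1]
        tracks[[t]]$union_px <- union(tracks[[t]]$union_px, cand$px)
        tracks[[t]]$last_frame <- i
        tracks[[t]]$entries[[length(tracks[[t]]$entries) + 1L]] <-
          list(frame = i, peak = cand$peak, rep_px = cand$rep_px)
      }
    }

    out$M[[i + 1]] <- M; out$N[[i + 1]] <- Ni; out$B[[i + 1]] <- B
    out$T_floor[i + 1] <- Tfl; out$D[[i + 1]] <- D; out$CD[[i + 1]] <- CD
    out$BM[[i + 1]] <- BM
    M_prev <- M; B_prev <- B
  }

  # finalize
  dets <- list()
  for (tr in tracks) {
    if (length(tr$entries) < params$min_detected_frames) next
    peaks <- sapply(tr$entries, `[[`, "peak")
    sel <- tr$entries[[which.max(peaks)]]
    yx <- arrayInd(sel$rep_px, c(H, W))
    dets[[length(dets) + 1L]] <- data.frame(
      det_id = tr$id, selected_frame = sel$frame,
      x = yx[2] - 1L, y = yx[1] - 1L,
      area_px = length(tr$union_px),
      n_frames = length(tr$entries),
      first_frame = tr$first_frame, last_frame = tr$last_frame)
  }
  out$detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(det_id = integer(), selected_frame = integer(),
               x = integer(), y = integer(), area_px = integer(),
               n_frames = integer(), first_frame = integer(),
               last_frame = integer())
  out
}

# Brute-force matcher implementing the documented matching semantics
# (greedy in ground-truth order of occurrence) with simple loops.
ref_match <- function(gt, det, max_dist = 20, max_dt = 15, fps = 8.66) {
  n_gt <- nrow(gt); n_det <- nrow(det)
  gt_status <- rep(NA_character_, n_gt)
  gt_pred <- rep(NA_character_, n_gt)
  det_role <- rep(NA_character_, n_det)
  taken <- rep(FALSE, n_det)
  idx_order <- if (n_gt > 0) order(gt$frame, seq_len(n_gt)) else integer(0)
  for (i in idx_order) {
    best <- NULL
    window <- c()
    for (j in seq_len(n_det)) {
      if (taken[j]) next
      d <- sqrt((det$x[j] - gt$x[i])^2 + (det$y[j] - gt$y[i])^2)
      dt <- abs(det$time_s[j] - gt$frame[i] / fps)
      if (d <= max_dist && dt <= max_dt) window <- c(window, j)
    }
    same <- window[det$label[window] == gt$label[i]]
    if (length(same)) {
      gt_status[i] <- "correct"; gt_pred[i] <- gt$label[i]
      det_role[same] <- "absorbed"; taken[same] <- TRUE
    } else if (length(window)) {
      d <- sqrt((det$x[window] - gt$x[i])^2 + (det$y[window] - gt$y[i])^2)
      dt <- abs(det$time_s[window] - gt$frame[i] / fps)
      j <- window[order(d, dt, det$det_id[window])][1]
      gt_status[i] <- "misclassified"; gt_pred[i] <- det$label[j]
      det_role[j] <- "misclassification"; taken[j] <- TRUE
    } else gt_status[i] <- "missed"
  }
  det_role[is.na(det_role) & det$label != "background"] <- "false_alarm"
  det_role[is.na(det_role) & det$label == "background"] <- "background"
  # confusion
  cm <- matrix(0L, 4, 3, dimnames = list(
    pred = c("urine", "feces", "background", "miss"),
    gt = c("urine", "feces", "background")))
  for (i in seq_len(n_gt)) {
    if (gt_status[i] == "missed") cm["miss", gt$label[i]] <-
        cm["miss", gt$label[i]] + 1L
    else cm[gt_pred[i], gt$label[i]] <- cm[gt_pred[i], gt$label[i]] + 1L
  }
  for (j in seq_len(n_det)) {
    if (det_role[j] == "false_alarm")
      cm[det$label[j], "background"] <- cm[det$label[j], "background"] + 1L
    if (det_role[j] == "background")
      cm["background", "background"] <- cm["background", "background"] + 1L
  }
  list(gt_status = gt_status, gt_pred = gt_pred, det_role = det_role, cm = cm)
}

# random matcher configuration generator (dense enough to hit the
# boundary and absorption cases)
random_match_config <- function(seed) {
  set.seed(seed)
  n_gt <- sample(0:8, 1)
  n_det <- sample(0:10, 1)
  labs <- c("urine", "feces")
  gt <- tibble::tibble(
    label = sample(labs, n_gt, replace = TRUE),
    frame = sample(0:600, n_gt, replace = TRUE),
    x = sample(0:60, n_gt, replace = TRUE),
    y = sample(0:60, n_gt, replace = TRUE))
  det <- tibble::tibble(
    det_id = seq_len(n_det),
    label = sample(c(labs, "background"), n_det, replace = TRUE),
    time_s = round(runif(n_det, 0, 70), 2),
    x = sample(0:60, n_det, replace = TRUE),
    y = sample(0:60, n_det, replace = TRUE))
  # push some detections exactly onto tolerance boundaries
  if (n_gt > 0 && n_det > 0) {
    j <- 1L
    det$x[j] <- gt$x[1] + 20; det$y[j] <- gt$y[1]
    det$time_s[j] <- gt$frame[1] / 8.66 + 15
  }
  list(gt = gt, det = det)
}
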