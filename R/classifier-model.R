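# The trainable patch-sequence classifier.
#
# Architecture (tiny backbone): each of the 26 patch triples is average-
# pooled and linearly embedded; its sinusoidal (x, y, t) encoding goes
# through the trainable 384 -> 256 affine map and a linear projection into
# the same embedding space; a tanh nonlinearity gives the token states; a
# single trainable query attends over the 26 token states (softmax
# attention) and the pooled state feeds a linear 3-way classification head.
# Everything is plain matrix algebra, trained full-batch with Adam.

#' Training schedules
#'
#' `reference_training_schedule()` is the full-scale recipe: two rounds
#' (230 epochs then 50 epochs on the enlarged training set, warm-started),
#' backbone learning rate 1e-5, 1e-4 for the remaining weights, with a
#' factor-10 drop after 200 and 40 epochs respectively.
#' `tiny_training_schedule()` is the desk-scale default used with the tiny
#' backbone.
#'
#' @param epochs,lr_backbone,lr_rest,drop_after,drop_factor Round
#'   parameters.
#' @return A list of rounds; each round is a list with those fields.
#' @export
tiny_training_schedule <- function(epochs = 120L, lr_backbone = 1e-3,
                                   lr_rest = 1e-3, drop_after = 100L,
                                   drop_factor = 0.1) {
  list(list(epochs = as.integer(epochs), lr_backbone = lr_backbone,
            lr_rest = lr_rest, drop_after = as.integer(drop_after),
            drop_factor = drop_factor))
}

#' @rdname tiny_training_schedule
#' @export
reference_training_schedule <- function() {
  list(list(epochs = 230L, lr_backbone = 1e-5, lr_rest = 1e-4,
            drop_after = 200L, drop_factor = 0.1),
       list(epochs = 50L, lr_backbone = 1e-5, lr_rest = 1e-4,
            drop_after = 40L, drop_factor = 0.1))
}

init_classifier_params <- function(config, f_dim) {
  d <- config$embed_dim
  e_in <- 3L * config$coord_embed_dim
  e_out <- config$joint_embed_dim
  g <- function(nr, nc, scale = 1) matrix(rnorm(nr * nc, 0, scale / sqrt(nr)), nr, nc)
  # the patch path is up-weighted and the position-time path down-weighted
  # at init so the class signal (small gray differences) is not buried
  # under the O(1) sinusoidal encodings
  list(W_enc = g(e_in, e_out), b_enc = numeric(e_out),
       W_p = g(f_dim, d, scale = 4), W_e = g(e_out, d, scale = 0.1),
       b = numeric(d),
       q = rnorm(d, 0, 1 / sqrt(d)),
       W_o = g(d, config$n_classes), b_o = numeric(config$n_classes))
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

softmax_cols <- function(m) {
  m <- exp(m - rep(apply(m, 2, max), each = nrow(m)))
  m / rep(colSums(m), each = nrow(m))
}

# forward pass over a stacked batch; Xb, Sb are (m * n_ex) x *, rows
# grouped by example
classifier_forward <- function(params, Xb, Sb, m, n_ex) {
  E <- Sb %*% params$W_enc +
    rep(params$b_enc, each = nrow(Sb))
  H <- tanh(Xb %*% params$W_p + E %*% params$W_e +
              rep(params$b, each = nrow(Xb)))
  s <- drop(H %*% params$q) / sqrt(length(params$q))
  A <- softmax_cols(matrix(s, m, n_ex))
  a_vec <- as.vector(A)
  ex_id <- rep(seq_len(n_ex), each = m)
  z <- rowsum(H * a_vec, ex_id)
  logits <- z %*% params$W_o + rep(params$b_o, each = n_ex)
  P <- softmax_rows(logits)
  list(P = P, cache = list(E = E, H = H, a_vec = a_vec, z = z,
                           ex_id = ex_id, m = m, n_ex = n_ex))
}

classifier_grads <- function(params, Xb, Sb, fwd, Y) {
  ch <- fwd$cache
  n_ex <- ch$n_ex; m <- ch$m
  dlogits <- (fwd$P - Y) / n_ex
  dW_o <- crossprod(ch$z, dlogits)
  db_o <- colSums(dlogits)
  dz <- dlogits %*% t(params$W_o)
  dz_big <- dz[ch$ex_id, , drop = FALSE]
  g <- rowSums(ch$H * dz_big)
  ag_sum <- colSums(matrix(ch$a_vec * g, m, n_ex))
  ds <- (ch$a_vec * (g - rep(ag_sum, each = m))) / sqrt(length(params$q))
  dH <- dz_big * ch$a_vec + outer(ds, params$q)
  dq <- drop(crossprod(ch$H, ds))
  dpre <- dH * (1 - ch$H^2)
  dW_p <- crossprod(Xb, dpre)
  dW_e <- crossprod(ch$E, dpre)
  db <- colSums(dpre)
  dE <- dpre %*% t(params$W_e)
  dW_enc <- crossprod(Sb, dE)
  db_enc <- colSums(dE)
  list(W_enc = dW_enc, b_enc = db_enc, W_p = dW_p, W_e = dW_e, b = db,
       q = dq, W_o = dW_o, b_o = db_o)
}

adam_step <- function(state, params, grads, lrs, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lrs[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

stack_examples <- function(examples, config, dim_hw) {
  feats <- purrr::map(examples, function(ex) {
    if (!is.null(ex$features)) ex$features
    else featurize_sequence(ex$seq, config, dim_hw)
  })
  m <- nrow(feats[[1]]$X)
  Xb <- do.call(rbind, purrr::map(feats, "X"))
  Sb <- do.call(rbind, purrr::map(feats, "S"))
  labels <- purrr::map_chr(examples, "label")
  list(Xb = Xb, Sb = Sb, m = m, n_ex = length(examples), labels = labels)
}

#' Train the patch-sequence classifier
#'
#' Trains the tiny-backbone classifier with full-batch Adam under the
#' given schedule (per-round epochs, separate backbone/rest learning
#' rates, factor drop late in each round). Training is deterministic for
#' a fixed seed.
#'
#' @param examples A list of training examples; each has `label` (one of
#'   urine/feces/background) and either `features` (from the internal
#'   featurizer) or `seq` (a `patch_sequence`).
#' @param config [classifier_config()].
#' @param schedule A schedule from [tiny_training_schedule()] or
#'   [reference_training_schedule()].
#' @param seed Integer seed for weight initialisation.
#' @param init Optional previously trained model to warm-start from
#'   (second-round training).
#' @param dim_hw `c(H, W)` of the source frames (for the position
#'   encoding scale).
#' @return An object of class `deposit_classifier` with the learned
#'   weights, the config/schedule echo and the per-epoch loss history.
#' @export
train_classifier <- function(examples, config = classifier_config(),
                             schedule = tiny_training_schedule(),
                             seed = config$seed, init = NULL,
                             dim_hw = NULL) {
  if (config$backbone != "tiny")
    abort(paste("Only the tiny backbone is implemented in this package;",
                "the reference configuration documents the full-scale",
                "architecture."))
  labels <- purrr::map_chr(examples, "label")
  missing <- setdiff(class_levels, unique(labels))
  if (length(missing))
    abort(sprintf("Training set lacks class(es): %s",
                  paste(missing, collapse = ", ")))
  batch <- stack_examples(examples, config, dim_hw)
  Y <- outer(batch$labels, class_levels, "==") * 1

  set.seed(seed)
  params <- if (is.null(init)) init_classifier_params(config, ncol(batch$Xb))
            else init$params
  state <- list(m = purrr::map(params, ~ .x * 0),
                v = purrr::map(params, ~ .x * 0))
  history <- list()
  t_step <- 0L
  for (round_i in seq_along(schedule)) {
    rd <- schedule[[round_i]]
    for (epoch in seq_len(rd$epochs)) {
      fac <- if (epoch > rd$drop_after) rd$drop_factor else 1
      fac <- fac * min(1, epoch / 5)  # short warmup tames the first Adam steps
      lrs <- list(W_enc = rd$lr_rest, b_enc = rd$lr_rest,
                  W_p = rd$lr_backbone, W_e = rd$lr_rest, b = rd$lr_rest,
                  q = rd$lr_rest, W_o = rd$lr_rest, b_o = rd$lr_rest)
      lrs <- purrr::map(lrs, ~ .x * fac)
      fwd <- classifier_forward(params, batch$Xb, batch$Sb, batch$m, batch$n_ex)
      loss <- -mean(log(pmax(fwd$P[cbind(seq_len(batch$n_ex),
                                         match(batch$labels, class_levels))],
                             1e-12)))
      if (!is.finite(loss)) abort("Non-finite training loss.")
      grads <- classifier_grads(params, batch$Xb, batch$Sb, fwd, Y)
      t_step <- t_step + 1L
      upd <- adam_step(state, params, grads, lrs, t_step)
      state <- upd$state; params <- upd$params
      history[[length(history) + 1L]] <-
        tibble(round = round_i, epoch = epoch, loss = loss)
    }
  }
  structure(list(params = params, config = config, schedule = schedule,
                 classes = class_levels,
                 history = dplyr::bind_rows(history),
                 seed = seed, n_train = batch$n_ex, dim_hw = dim_hw),
            class = "deposit_classifier")
}

#' @export
print.deposit_classifier <- function(x, ...) {
  cat(sprintf(
    "<deposit_classifier> %s backbone, %d training examples, final loss %.4f\n",
    x$config$backbone, x$n_train, tail(x$history$loss, 1)))
  invisible(x)
}

#' Classify one patch sequence
#'
#' @param model A trained `deposit_classifier`.
#' @param seq A `patch_sequence` from [extract_patch_sequence()].
#' @return A list with `label` (argmax class) and `scores` (named numeric,
#'   summing to 1).
#' @export
classify_detection <- function(model, seq) {
  feats <- featurize_sequence(seq, model$config, model$dim_hw)
  fwd <- classifier_forward(model$params, feats$X, feats$S, nrow(feats$X), 1L)
  scores <- drop(fwd$P)
  names(scores) <- model$classes
  list(label = model$classes[which.max(scores)], scores = scores)
}

#' Classify all preliminary detections of a session
#'
#' Extracts the patch sequence of each detection (anchored at its
#' representative pixel and selected frame) and appends the predicted
#' label and per-class scores to the detections table.
#'
#' @param model A trained `deposit_classifier`.
#' @param video The session's calibrated [thermal_video()].
#' @param detections Tibble from [run_preliminary_detection()].
#' @return The detections tibble with `label`, `score_urine`,
#'   `score_feces`, `score_background` columns added.
#' @export
classify_detections <- function(model, video, detections) {
  if (nrow(detections) == 0L)
    return(dplyr::mutate(detections, label = character(0),
                         score_urine = double(0), score_feces = double(0),
                         score_background = double(0)))
  res <- purrr::map(seq_len(nrow(detections)), function(i) {
    seq <- extract_patch_sequence(video, detections$x[i], detections$y[i],
                                  detections$selected_frame[i], model$config)
    classify_detection(model, seq)
  })
  detections$label <- purrr::map_chr(res, "label")
  detections$score_urine <- purrr::map_dbl(res, ~ .x$scores[["urine"]])
  detections$score_feces <- purrr::map_dbl(res, ~ .x$scores[["feces"]])
  detections$score_background <- purrr::map_dbl(res, ~ .x$scores[["background"]])
  detections
}

#' Collect training examples from sessions
#'
#' Walks a training manifest (see [build_training_set()]) and extracts the
#' featurized examples from each session's video, optionally with one
#' drawn augmentation per example and extra augmented copies of the
#' positives (the positive class is otherwise outnumbered by the 40 random
#' negatives per session).
#'
#' @param sessions Named list of sessions (see [build_training_set()]);
#'   names must match the manifest's `video_id`.
#' @param manifest Tibble from [build_training_set()].
#' @param config [classifier_config()].
#' @param augment Draw one augmentation per example?
#' @param positive_copies Total copies of each positive (1 = no extras).
#' @param seed Integer seed.
#' @return A list of featurized examples for [train_classifier()].
#' @export
collect_training_examples <- function(sessions, manifest,
                                      config = classifier_config(),
                                      augment = TRUE, positive_copies = 3L,
                                      seed = 1L) {
  set.seed(seed)
  out <- list()
  for (sid in unique(manifest$video_id)) {
    s <- sessions[[sid]]
    if (is.null(s)) abort(sprintf("Manifest references unknown session '%s'.", sid))
    video <- s$video
    dim_hw <- c(video$height, video$width)
    rows <- manifest[manifest$video_id == sid, ]
    for (i in seq_len(nrow(rows))) {
      n_copies <- if (rows$provenance[i] == "manual_positive")
        positive_copies else 1L
      for (cp in seq_len(n_copies)) {
        ex <- list(label = rows$label[i], provenance = rows$provenance[i],
                   video_id = sid,
                   seq = extract_patch_sequence(video, rows$x[i], rows$y[i],
                                                rows$frame[i], config))
        if (augment) ex <- augment_example(ex, video, config)
        ex$features <- featurize_sequence(ex$seq, config, dim_hw)
        ex$seq <- NULL  # keep memory bounded
        out[[length(out) + 1L]] <- ex
      }
    }
  }
  out
}

#' Save and load a trained classifier
#'
#' The model card (`<base>.card.json`) records the configuration,
#' schedule, seed, class map and final loss; the weights are stored in
#' `<base>.rds`.
#'
#' @param model A `deposit_classifier`.
#' @param base Path without extension.
#' @export
write_model <- function(model, base) {
  saveRDS(model, paste0(base, ".rds"))
  card <- list(backbone = model$config$backbone,
               classes = as.list(model$classes),
               n_train = model$n_train,
               seed = model$seed,
               schedule = model$schedule,
               config = model$config[c("coord_embed_dim", "joint_embed_dim",
                                       "n_queries", "n_classes", "patch_px",
                                       "frame_stride", "pad_temp_C",
                                       "pool_px", "embed_dim")],
               final_loss = tail(model$history$loss, 1))
  write_json_canonical(card, paste0(base, ".card.json"))
  invisible(base)
}

#' @rdname write_model
#' @export
read_model <- function(base) {
  readRDS(paste0(base, ".rds"))
}
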