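#' Classifier configuration
#'
#' Configuration of the patch-sequence classifier. Each preliminary
#' detection is represented by 78 grayscale patches of `patch_px` x
#' `patch_px` pixels cropped around the detection pixel at frames
#' `i + k * frame_stride`, `k` in `k_range` — a time window of roughly
#' -11 s to +60 s at 8.66 fps, wide enough to capture the deposition
#' moment (which may precede the detection when the mouse occludes it) and
#' the full cooldown. Temperatures are normalized linearly so that
#' `norm_range_C[1]` maps to 0 and `norm_range_C[2]` to 255, clipped;
#' missing frames (and pixels outside the image) are padded with a uniform
#' `pad_temp_C` patch. Consecutive patch triples are packed as the three
#' channels of one image, giving 26 tokens; each token carries a sinusoidal
#' position-time encoding of (x, y, t), three 128-long encodings joined by
#' a trainable affine map to `joint_embed_dim`. A single query attends over
#' the 26 tokens and a classification head emits urine/feces/background
#' scores.
#'
#' The `tiny` backbone embeds each token by average-pooling its channels to
#' `pool_px` x `pool_px` and applying a trainable linear map to
#' `embed_dim`; it is the desk-scale configuration used throughout the
#' package's tests. The `reference` backbone name records the full-scale
#' architecture this mirrors (a 50-layer residual network with a dilated
#' final stage feeding a transformer encoder-decoder); it is not shipped
#' here and selecting it signals an error.
#'
#' @param backbone `"tiny"` or `"reference"`.
#' @param coord_embed_dim Sinusoidal encoding length per axis (128).
#' @param joint_embed_dim Joint position-time encoding length (256).
#' @param n_queries Number of decoder queries (fixed at 1: classification
#'   only, no bounding boxes).
#' @param n_classes Number of classes (urine, feces, background).
#' @param patch_px Patch side length in pixels (65).
#' @param frame_stride Frame subsampling stride (8).
#' @param k_range Patch offsets in strides (`-12:65`, 78 patches).
#' @param pad_temp_C Padding temperature for missing frames/pixels (22).
#' @param norm_range_C Temperatures mapped to gray levels 0 and 255.
#' @param pool_px Tiny-backbone pooled patch side (13).
#' @param embed_dim Tiny-backbone token embedding dimension (32).
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("tiny", "reference"),
                              coord_embed_dim = 128L,
                              joint_embed_dim = 256L,
                              n_queries = 1L,
                              n_classes = 3L,
                              patch_px = 65L,
                              frame_stride = 8L,
                              k_range = -12:65,
                              pad_temp_C = 22,
                              norm_range_C = c(10, 40),
                              pool_px = 13L,
                              embed_dim = 32L,
                              seed = 1L) {
  backbone <- match.arg(backbone)
  if (n_queries != 1L) abort("The classifier uses a single query.")
  if (length(k_range) %% 3L != 0L)
    abort("`k_range` length must be divisible by 3 (patch triples).")
  if (patch_px %% 2L == 0L) abort("`patch_px` must be odd.")
  structure(list(backbone = backbone,
                 coord_embed_dim = as.integer(coord_embed_dim),
                 joint_embed_dim = as.integer(joint_embed_dim),
                 n_queries = 1L, n_classes = as.integer(n_classes),
                 patch_px = as.integer(patch_px),
                 frame_stride = as.integer(frame_stride),
                 k_range = as.integer(k_range),
                 pad_temp_C = pad_temp_C, norm_range_C = norm_range_C,
                 pool_px = as.integer(pool_px),
                 embed_dim = as.integer(embed_dim),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

class_levels <- c("urine", "feces", "background")

# linear gray mapping with clipping
normalize_temperature <- function(temp, config) {
  lo <- config$norm_range_C[1]; hi <- config$norm_range_C[2]
  g <- (temp - lo) / (hi - lo) * 255
  pmin(pmax(g, 0), 255)
}

#' Extract a patch sequence around a detection
#'
#' Crops `length(k_range)` patches of `patch_px` x `patch_px` pixels
#' centered on `(x, y)` from frames `frame + k * frame_stride`. Frames
#' outside the video and pixels outside the image are padded with the
#' uniform padding temperature. All values are normalized to gray levels
#' (0..255).
#'
#' @param video A [thermal_video()].
#' @param x,y Anchor pixel (0-based).
#' @param frame Anchor frame (0-based); for a preliminary detection, its
#'   selected frame.
#' @param config [classifier_config()].
#' @return A list of class `patch_sequence`: `patches` (array `patch_px x
#'   patch_px x n_patches`), `anchor` (`c(x, y, frame)`), `valid` (logical,
#'   `FALSE` where the whole patch is padding).
#' @export
extract_patch_sequence <- function(video, x, y, frame,
                                   config = classifier_config()) {
  H <- video$height; W <- video$width; n <- n_frames(video)
  if (x < 0 || x >= W || y < 0 || y >= H)
    abort("Anchor pixel outside the image.")
  half <- (config$patch_px - 1L) %/% 2L
  np <- length(config$k_range)
  pad_gray <- normalize_temperature(config$pad_temp_C, config)
  patches <- array(pad_gray, dim = c(config$patch_px, config$patch_px, np))
  valid <- logical(np)
  rows <- (y - half):(y + half)  # 0-based
  cols <- (x - half):(x + half)
  r_ok <- rows >= 0 & rows < H
  c_ok <- cols >= 0 & cols < W
  for (t in seq_len(np)) {
    fi <- frame + config$k_range[t] * config$frame_stride
    if (fi < 0 || fi >= n) next
    valid[t] <- TRUE
    src <- video$frames[rows[r_ok] + 1L, cols[c_ok] + 1L, fi + 1L]
    patches[which(r_ok), which(c_ok), t] <- normalize_temperature(src, config)
  }
  structure(list(patches = patches, anchor = c(x = x, y = y, frame = frame),
                 valid = valid),
            class = "patch_sequence")
}

#' Pack patch triples into multi-channel images
#'
#' Consecutive patches `(3k, 3k+1, 3k+2)` become channels 1..3 of image
#' `k` (temporal order preserved), mirroring how three grayscale patches
#' are packed into one RGB image for an image backbone. `unpack_triples()`
#' inverts exactly.
#'
#' @param seq A `patch_sequence` or a patches array.
#' @return Array `patch_px x patch_px x 3 x n_triples`.
#' @export
pack_triples <- function(seq) {
  patches <- if (inherits(seq, "patch_sequence")) seq$patches else seq
  np <- dim(patches)[3]
  array(patches, dim = c(dim(patches)[1], dim(patches)[2], 3L, np %/% 3L))
}

#' @rdname pack_triples
#' @param triples Array from [pack_triples()].
#' @export
unpack_triples <- function(triples) {
  d <- dim(triples)
  array(triples, dim = c(d[1], d[2], d[3] * d[4]))
}

# sinusoidal encoding of one scalar (scaled to [0, 2*pi]) with `dim`
# components: dim/2 sine / cosine pairs at geometrically spaced frequencies
sinusoid_encoding <- function(value, dim, temperature = 10000) {
  half <- dim %/% 2L
  freq <- temperature^(-(seq_len(half) - 1) / half)
  ang <- value * freq
  c(sin(ang), cos(ang))
}

#' Position-time encoding
#'
#' Sinusoidal encodings of the anchor position and the token time — the
#' time axis encoded with the same functional form as a spatial axis —
#' concatenated (3 x `coord_embed_dim` = 384) and passed through one
#' trainable affine map to `joint_embed_dim` (256).
#'
#' @param x_idx,y_idx Anchor pixel scaled to `[0, 2*pi]` over the frame.
#' @param t_idx Token time index scaled to `[0, 2*pi]` over the sequence.
#' @param weights List with `W` (`384 x joint_embed_dim`) and `b`; see
#'   [init_encoding_weights()].
#' @param config [classifier_config()].
#' @return Numeric vector of length `joint_embed_dim`.
#' @export
position_time_encoding <- function(x_idx, y_idx, t_idx, weights,
                                   config = classifier_config()) {
  raw <- position_time_encoding_raw(x_idx, y_idx, t_idx, config)
  drop(raw %*% weights$W) + weights$b
}

position_time_encoding_raw <- function(x_idx, y_idx, t_idx, config) {
  d <- config$coord_embed_dim
  c(sinusoid_encoding(x_idx, d), sinusoid_encoding(y_idx, d),
    sinusoid_encoding(t_idx, d))
}

#' @rdname position_time_encoding
#' @export
init_encoding_weights <- function(config = classifier_config()) {
  d_in <- 3L * config$coord_embed_dim
  d_out <- config$joint_embed_dim
  list(W = matrix(rnorm(d_in * d_out, 0, 1 / sqrt(d_in)), d_in, d_out),
       b = numeric(d_out))
}

# ---- tiny-backbone featurization -------------------------------------------

# average-pool a patch_px x patch_px x 3 triple to pool_px x pool_px x 3
pool_triple <- function(tri, pool_px) {
  p <- dim(tri)[1]
  # pool over `pool_px` near-equal pixel bins per axis
  bins <- as.integer(cut(seq_len(p), pool_px))
  pooled <- apply(tri, 3, function(ch)
    rowsum(t(rowsum(ch, bins)), bins) / tabulate(bins)^2)
  array(pooled, dim = c(pool_px, pool_px, 3L))
}

# Token features and raw encodings for one sequence:
#   X: n_tokens x (2 * 3 * pool_px^2): the full patch average-pooled to
#      pool_px, plus a full-resolution central pool_px crop (small deposits
#      span only a few pixels and vanish under pooling alone); gray values
#      scaled to [-0.4, 0.6] with the padding gray at 0
#   S: n_tokens x 384, raw sinusoidal (x, y, t) encodings
featurize_sequence <- function(seq, config, dim_hw = NULL) {
  tri <- pack_triples(seq)
  m <- dim(tri)[4]
  pad_gray <- normalize_temperature(config$pad_temp_C, config)
  half <- (dim(tri)[1] - 1L) %/% 2L
  ctr <- (half + 1L) + seq(-(config$pool_px - 1L) %/% 2L,
                           (config$pool_px - 1L) %/% 2L)
  X <- matrix(0, m, 6L * config$pool_px^2)
  for (k in seq_len(m)) {
    pooled <- as.vector(pool_triple(tri[, , , k], config$pool_px))
    centre <- as.vector(tri[ctr, ctr, , k])
    X[k, ] <- (c(pooled, centre) - pad_gray) / 255
  }
  anchor <- seq$anchor
  if (is.null(dim_hw)) dim_hw <- c(max(anchor["y"] + 1, 1), max(anchor["x"] + 1, 1))
  xs <- 2 * pi * anchor[["x"]] / max(dim_hw[2], 1)
  ys <- 2 * pi * anchor[["y"]] / max(dim_hw[1], 1)
  S <- t(vapply(seq_len(m), function(k)
    position_time_encoding_raw(xs, ys, 2 * pi * (k - 1) / m, config),
    numeric(3L * config$coord_embed_dim)))
  list(X = X, S = S)
}
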