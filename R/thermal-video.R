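#' Radiometric thermal video
#'
#' A `thermal_video` holds a time-ordered stack of per-pixel apparent
#' temperature frames (degrees Celsius) together with the frame rate and
#' per-frame timestamps. It is the raw input of the deposition pipeline.
#'
#' @param frames A numeric array `H x W x n` of temperatures in deg C, or a
#'   list of `H x W` matrices sharing one shape.
#' @param fps Frame rate in frames per second (nominal 8.66 for the
#'   long-wave camera this pipeline targets).
#' @param timestamps Optional numeric vector of per-frame times in seconds,
#'   strictly increasing. Defaults to `(0:(n-1)) / fps`.
#'
#' @return An object of class `thermal_video` with fields `frames`
#'   (`H x W x n` array), `fps`, `timestamps`, `height`, `width`.
#' @export
thermal_video <- function(frames, fps = 8.66, timestamps = NULL) {
  if (is.list(frames)) {
    shapes <- vapply(frames, dim, integer(2))
    if (length(frames) == 0L) abort("`frames` must contain at least one frame.")
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      abort("All frames must share one shape.")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[1, 1], shapes[2, 1], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort("`frames` must be an H x W x n array or a list of matrices.")
  stopifnot_scalar_number(fps, "fps", positive = TRUE)
  n <- dim(frames)[3]
  if (!all(is.finite(frames))) abort("All temperatures must be finite.")
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / fps
  if (length(timestamps) != n) abort("`timestamps` must have one entry per frame.")
  if (n > 1 && any(diff(timestamps) <= 0))
    abort("`timestamps` must be strictly increasing.")
  structure(
    list(frames = frames, fps = fps, timestamps = as.numeric(timestamps),
         height = dim(frames)[1], width = dim(frames)[2]),
    class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  cat(sprintf("<thermal_video> %d x %d px, %d frames @ %.3g fps (%.1f s)\n",
              x$width, x$height, n_frames(x), x$fps,
              n_frames(x) / x$fps))
  invisible(x)
}

#' @rdname thermal_video
#' @param video A `thermal_video`.
#' @export
n_frames <- function(video) dim(video$frames)[3]

# i is a 0-based frame index
frame_at <- function(video, i) video$frames[, , i + 1L]

#' Compute a non-uniformity correction image
#'
#' Averages frames captured of a uniform surface (e.g. a piece of cardboard
#' held in front of the lens) and removes the scalar mean, yielding a
#' zero-mean per-pixel offset image that captures the sensor's fixed-pattern
#' non-uniformity.
#'
#' @param uniform_frames An `H x W x n` array or list of matrices of
#'   apparent temperatures of a uniform scene.
#' @return An `H x W` matrix with mean exactly zero (up to rounding).
#' @export
compute_nuc_image <- function(uniform_frames) {
  if (is.list(uniform_frames)) {
    if (length(uniform_frames) == 0L) abort("Need at least one uniform frame.")
    shapes <- vapply(uniform_frames, dim, integer(2))
    if (any(shapes != shapes[, 1])) abort("Uniform frames must share one shape.")
    uniform_frames <- array(unlist(uniform_frames, use.names = FALSE),
                            dim = c(shapes[1, 1], shapes[2, 1],
                                    length(uniform_frames)))
  }
  if (!is.array(uniform_frames) || length(dim(uniform_frames)) != 3L)
    abort("`uniform_frames` must be an H x W x n array or list of matrices.")
  avg <- rowMeans(uniform_frames, dims = 2)
  avg - mean(avg)
}

#' Calibration bundle
#'
#' Bundles the per-pixel non-uniformity image, the blackbody region mask and
#' the blackbody setpoint used by [apply_calibration()].
#'
#' @param nuc_image `H x W` zero-mean offset image (deg C); see
#'   [compute_nuc_image()].
#' @param blackbody_mask `H x W` logical mask of the blackbody region
#'   (at least one pixel).
#' @param blackbody_setpoint Blackbody temperature in deg C (default 37).
#' @return An object of class `calibration_bundle`.
#' @export
calibration_bundle <- function(nuc_image, blackbody_mask,
                               blackbody_setpoint = 37) {
  if (!is.matrix(nuc_image)) abort("`nuc_image` must be a matrix.")
  if (abs(mean(nuc_image)) >= 1e-9)
    abort("`nuc_image` must have zero mean (see compute_nuc_image()).")
  if (!is.logical(blackbody_mask) || !identical(dim(blackbody_mask), dim(nuc_image)))
    abort("`blackbody_mask` must be a logical matrix matching `nuc_image`.")
  if (!any(blackbody_mask)) abort("`blackbody_mask` must contain >= 1 pixel.")
  stopifnot_scalar_number(blackbody_setpoint, "blackbody_setpoint")
  structure(list(nuc_image = nuc_image, blackbody_mask = blackbody_mask,
                 blackbody_setpoint = blackbody_setpoint),
            class = "calibration_bundle")
}

#' Apply radiometric calibration
#'
#' Subtracts the fixed-pattern non-uniformity image from every frame, then
#' removes per frame the scalar offset between the blackbody region's mean
#' apparent temperature and the blackbody setpoint. The per-frame offset
#' cancels slow sensor drift; after calibration the blackbody region reads
#' the setpoint on average in every frame.
#'
#' @param video A [thermal_video()].
#' @param calib A [calibration_bundle()] whose shapes match the video.
#' @param per_frame If `TRUE` (default) the blackbody offset is computed per
#'   frame; if `FALSE` a single session-wide offset (mean over frames) is
#'   used.
#' @return A calibrated `thermal_video`.
#' @export
apply_calibration <- function(video, calib, per_frame = TRUE) {
  stopifnot(inherits(video, "thermal_video"), inherits(calib, "calibration_bundle"))
  if (!identical(dim(calib$nuc_image), dim(video$frames)[1:2]))
    abort("Calibration shapes do not match the video.")
  n <- n_frames(video)
  frames <- video$frames - as.vector(calib$nuc_image)  # recycles over frames
  bb <- which(calib$blackbody_mask)
  flat <- matrix(frames, ncol = n)
  offsets <- colMeans(flat[bb, , drop = FALSE]) - calib$blackbody_setpoint
  if (!per_frame) offsets <- rep(mean(offsets), n)
  frames <- frames - rep(offsets, each = prod(dim(video$frames)[1:2]))
  thermal_video(frames, fps = video$fps, timestamps = video$timestamps)
}

# ---- container I/O ---------------------------------------------------------
#
# One session = <base>.tif (multi-frame 16-bit grayscale) + <base>.meta.json
# holding {scale, offset, fps, width, height, n_frames, timestamps?}.
# T(degC) = raw * scale + offset; defaults scale = 0.01, offset = 0, i.e.
# a quantization step of 0.01 degC.

#' Read and write the thermal-video container
#'
#' A session is stored as a multi-frame 16-bit grayscale TIFF plus a JSON
#' sidecar `<base>.meta.json` with fields `scale`, `offset`, `fps`, `width`,
#' `height`, `n_frames` and optional `timestamps`. Temperatures map to raw
#' counts as `raw = round((T - offset) / scale)`; the default `scale = 0.01`
#' gives a 0.01 deg C quantization step. When the sidecar omits timestamps,
#' frame `k` (0-based) is assigned time `k / fps`.
#'
#' @param video A [thermal_video()].
#' @param base Path without extension; `<base>.tif` and `<base>.meta.json`
#'   are written/read.
#' @param scale,offset Radiometric quantization used on disk.
#' @param write_timestamps If `TRUE`, explicit timestamps are stored in the
#'   sidecar. If `FALSE`, they are stored only when they differ from the
#'   `k / fps` default.
#' @return `write_thermal_video()` returns `base` invisibly;
#'   `read_thermal_video()` returns a `thermal_video`.
#' @export
write_thermal_video <- function(video, base, scale = 0.01, offset = 0,
                                write_timestamps = FALSE) {
  stopifnot(inherits(video, "thermal_video"))
  raw <- round((video$frames - offset) / scale)
  if (any(raw < 0) || any(raw > 65535))
    abort("Temperatures outside the representable range for this scale/offset.")
  n <- n_frames(video)
  pages <- lapply(seq_len(n), function(i) raw[, , i] / 65535)
  tiff::writeTIFF(pages, paste0(base, ".tif"), bits.per.sample = 16,
                  compression = "none")
  default_ts <- (seq_len(n) - 1) / video$fps
  meta <- list(scale = scale, offset = offset, fps = video$fps,
               width = video$width, height = video$height, n_frames = n)
  if (write_timestamps || max(abs(video$timestamps - default_ts)) > 1e-9)
    meta$timestamps <- video$timestamps
  write_json_canonical(meta, paste0(base, ".meta.json"))
  invisible(base)
}

#' @rdname write_thermal_video
#' @export
read_thermal_video <- function(base) {
  tif <- paste0(base, ".tif")
  sidecar <- paste0(base, ".meta.json")
  if (!file.exists(tif)) abort(sprintf("Missing container: %s", tif))
  if (!file.exists(sidecar)) abort(sprintf("Missing sidecar: %s", sidecar))
  meta <- read_json(sidecar)
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames)
    abort(sprintf("Container has %d frames but sidecar declares %d.",
                  length(pages), meta$n_frames))
  if (nrow(pages[[1]]) != meta$height || ncol(pages[[1]]) != meta$width)
    abort("Frame shape does not match the sidecar.")
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(meta$height, meta$width, meta$n_frames))
  frames <- frames * meta$scale + meta$offset
  thermal_video(frames, fps = meta$fps, timestamps = meta$timestamps)
}

#' Read and write a calibration bundle
#'
#' Stored as `<base>.nuc.tif` (16-bit TIFF of the non-uniformity image, with
#' its own scale/offset recorded in the sidecar), `<base>.bb.png` (blackbody
#' mask) and `<base>.calib.json`. Because the non-uniformity image is
#' quantized on disk, it is re-centred to zero mean on load.
#'
#' @param calib A [calibration_bundle()].
#' @param base Path without extension.
#' @export
write_calibration <- function(calib, base) {
  stopifnot(inherits(calib, "calibration_bundle"))
  rng <- range(calib$nuc_image)
  off <- rng[1]
  sc <- max((rng[2] - rng[1]) / 65535, 1e-6)
  raw <- round((calib$nuc_image - off) / sc)
  tiff::writeTIFF(raw / 65535, paste0(base, ".nuc.tif"), bits.per.sample = 16,
                  compression = "none")
  png::writePNG(calib$blackbody_mask * 1, paste0(base, ".bb.png"))
  write_json_canonical(
    list(nuc_scale = sc, nuc_offset = off,
         blackbody_setpoint = calib$blackbody_setpoint),
    paste0(base, ".calib.json"))
  invisible(base)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(base) {
  meta <- read_json(paste0(base, ".calib.json"))
  raw <- round(tiff::readTIFF(paste0(base, ".nuc.tif"), as.is = TRUE))
  nuc <- raw * meta$nuc_scale + meta$nuc_offset
  nuc <- nuc - mean(nuc)  # restore exact zero mean lost to quantization
  mask <- png::readPNG(paste0(base, ".bb.png")) > 0.5
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  calibration_bundle(nuc, mask, meta$blackbody_setpoint)
}
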