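# Internal helpers shared across modules.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based, x = column, y = row, origin top-left;
#   * frame indices are 0-based; all intervals are closed [first, last];
#   * temperatures are degrees Celsius; times are seconds.
# R matrices are 1-based, so `y + 1` / `x + 1` / `frame + 1` appear at the
# boundary between public values and internal array indexing.

s_to_frames <- function(seconds, fps) as.integer(round(seconds * fps))

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}

# Lower median: for an even count the smaller of the two central order
# statistics, i.e. sorted[ceiling(n/2)].
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) abort("lower_median() of an empty vector.")
  sort.int(x, partial = ceiling(n / 2))[ceiling(n / 2)]
}

# Index (1-based) of the maximum of a matrix, ties broken row-major:
# smallest row (y), then smallest column (x).
argmax_row_major <- function(m) {
  mx <- max(m)
  hits <- which(m == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  hits[1L, ]
}

# Deterministic JSON writer: fixed key order (as supplied), no scientific
# notation drift, trailing newline. Used for all sidecars and reports so
# reruns are byte-identical.
write_json_canonical <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = 2,
                          null = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# write_csv with fixed options so reruns are byte-identical
write_csv_stable <- function(df, path) {
  readr::write_csv(df, path, eol = "\n", progress = FALSE)
  invisible(path)
}
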