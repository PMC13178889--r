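#' Construct a plantar pressure recording
#'
#' A `pressure_recording` is a time-ordered stack of sensor-grid pressure
#' frames together with its physical metadata. Frames are stored as a
#' `T x H x W` numeric array of pressures in kPa; the row index runs along the
#' walking-progression axis (the long side of the footplate), the column
#' index is mediolateral. Public coordinates are 0-based sensor units: the
#' sensor at array position `[r + 1, c + 1]` has coordinates `(row = r,
#' col = c)`.
#'
#' Pressures below the hardware detection threshold (10 kPa) are stored as
#' exactly 0 so that "activated sensor" is unambiguous downstream.
#'
#' @param frames Numeric array `T x H x W` of pressures (kPa), or a matrix
#'   (interpreted as a single frame).
#' @param pitch_mm Sensor spacing in mm (> 0). Default 5.
#' @param rate_hz Sampling frequency in Hz (> 0). Default 100.
#' @param id Participant/trial identifier string.
#' @param threshold Apply the 10 kPa detection threshold (zero sub-threshold
#'   values) on construction. Default `TRUE`.
#' @return An object of class `pressure_recording`.
#' @export
#' @examples
#' fr <- array(0, c(3, 4, 4)); fr[2, 2, 2] <- 50
#' rec <- pressure_recording(fr, id = "demo")
#' total_force(rec)
pressure_recording <- function(frames, pitch_mm = SENSOR_PITCH_MM,
                               rate_hz = SAMPLING_RATE_HZ, id = "rec",
                               threshold = TRUE) {
  if (is.matrix(frames)) {
    frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a T x H x W array or a single matrix.")
  }
  stopifnot_scalar_number(pitch_mm, "pitch_mm", positive = TRUE)
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (anyNA(frames)) abort("`frames` must not contain missing values.")
  if (min(frames) < 0) {
    neg <- which(frames < 0, arr.ind = TRUE)
    abort(sprintf("negative pressure value at frame %d (row %d, col %d)",
                  neg[1, 1], neg[1, 2], neg[1, 3]))
  }
  if (threshold) frames[frames < DETECTION_THRESHOLD_KPA] <- 0
  structure(
    list(frames = frames, pitch_mm = pitch_mm, rate_hz = rate_hz,
         id = as.character(id)),
    class = "pressure_recording"
  )
}

#' @export
print.pressure_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<pressure_recording '%s'> %d frames of %d x %d sensors (%g mm pitch, %g Hz)\n",
    x$id, d[1], d[2], d[3], x$pitch_mm, x$rate_hz))
  cat(sprintf("  active sensors (any frame): %d; max pressure: %.1f kPa\n",
              sum(apply(x$frames > 0, c(2, 3), any)), max(x$frames)))
  invisible(x)
}

#' Total vertical force per frame
#'
#' Sums pressure times sensor area over the grid for each frame:
#' `force (N) = sum(kPa) * 1000 Pa/kPa * area (m^2)`. With 5 mm pitch
#' (25 mm^2 cells) a single sensor at 10 kPa carries 0.25 N.
#'
#' @param rec A `pressure_recording`, or a `T x H x W` array of kPa values.
#' @param cell_area_mm2 Cell area in mm^2; defaults to `pitch^2` of the
#'   recording (25 for the raw sensor grid).
#' @return Numeric vector of per-frame forces in newtons.
#' @export
total_force <- function(rec, cell_area_mm2 = NULL) {
  if (inherits(rec, "pressure_recording")) {
    if (is.null(cell_area_mm2)) cell_area_mm2 <- rec$pitch_mm^2
    frames <- rec$frames
  } else {
    frames <- rec
    if (is.null(cell_area_mm2)) cell_area_mm2 <- SENSOR_AREA_MM2
  }
  d <- dim(frames)
  rowSums(matrix(frames, d[1], d[2] * d[3])) * 1000 * cell_area_mm2 * 1e-6
}

format_num <- function(x) {
  # fixed, locale-independent formatting so repeated writes are byte-identical
  out <- formatC(x, format = "g", digits = 9)
  gsub("^\\s+", "", out)
}

#' Write a recording to the plain-text frame-stack format
#'
#' The format is a `key: value` header (`pitch_mm`, `rate_hz`, `n_frames`,
#' `n_rows`, `n_cols`, `id`) followed by one whitespace-separated `H x W`
#' matrix per frame, frames separated by blank lines. Writing the same
#' recording twice yields byte-identical files.
#'
#' @param rec A valid `pressure_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "pressure_recording")) abort("`rec` must be a pressure_recording.")
  d <- dim(rec$frames)
  header <- c(
    paste0("pitch_mm: ", format_num(rec$pitch_mm)),
    paste0("rate_hz: ", format_num(rec$rate_hz)),
    paste0("n_frames: ", d[1]),
    paste0("n_rows: ", d[2]),
    paste0("n_cols: ", d[3]),
    paste0("id: ", rec$id)
  )
  blocks <- vapply(seq_len(d[1]), function(t) {
    m <- matrix(rec$frames[t, , ], d[2], d[3])
    paste(apply(m, 1, function(r) paste(format_num(r), collapse = " ")),
          collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, "", paste(blocks, collapse = "\n\n")), con, sep = "\n")
  invisible(path)
}

#' Read a recording from the frame-stack format
#'
#' Parses the text format written by [write_recording()]. Pressures below the
#' 10 kPa detection threshold are zeroed at read time; negative values raise
#' a validation error naming the offending frame.
#'
#' @param path Path to a frame-stack file.
#' @return A `pressure_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr_end <- which(lines == "")[1]
  if (is.na(hdr_end)) abort("frame-stack format error: missing blank line after header")
  hdr_lines <- lines[seq_len(hdr_end - 1)]
  kv <- strsplit(hdr_lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  need <- c("pitch_mm", "rate_hz", "n_frames", "n_rows", "n_cols")
  missing <- setdiff(need, keys)
  if (length(missing) > 0) {
    abort(sprintf("frame-stack format error: missing header field '%s'", missing[1]))
  }
  get_num <- function(k) {
    v <- suppressWarnings(as.numeric(vals[match(k, keys)]))
    if (is.na(v)) abort(sprintf("frame-stack format error: invalid value for '%s'", k))
    v
  }
  n_frames <- as.integer(get_num("n_frames"))
  n_rows <- as.integer(get_num("n_rows"))
  n_cols <- as.integer(get_num("n_cols"))
  id <- if ("id" %in% keys) vals[match("id", keys)] else "rec"
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[body != ""]
  if (length(body) != n_frames * n_rows) {
    abort(sprintf("frame-stack format error: expected %d data rows, found %d",
                  n_frames * n_rows, length(body)))
  }
  vals_num <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals_num) != n_frames * n_rows * n_cols) {
    abort("frame-stack format error: wrong number of values")
  }
  frames <- array(0, c(n_frames, n_rows, n_cols))
  for (t in seq_len(n_frames)) {
    seg <- vals_num[((t - 1) * n_rows * n_cols + 1):(t * n_rows * n_cols)]
    frames[t, , ] <- matrix(seg, n_rows, n_cols, byrow = TRUE)
  }
  pressure_recording(frames, pitch_mm = get_num("pitch_mm"),
                     rate_hz = get_num("rate_hz"), id = id)
}

#' Write a cohort manifest
#'
#' One CSV row per participant with demographics (`id`, `sex` spelled
#' "female"/"male", `age`, `height`, `weight`, `bmi`), the recording path,
#' and per-foot landmark coordinates in 0-based sensor units
#' (`{left,right}_l1_row`, `..._l1_col`, `..._l2_row`, `..._l2_col`;
#' Landmark 1 = most posterior heel point, Landmark 2 = tip of the second
#' toe).
#'
#' @param manifest A tibble with the columns above (`recording` may hold
#'   paths; list-columns are dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  keep <- !vapply(manifest, is.list, logical(1))
  readr::write_csv(manifest[keep], path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest CSV path written by [write_manifest()].
#' @return A tibble, with `sex` validated to "female"/"male", unique ids,
#'   and BMI checked against height/weight (within 0.1) where all three are
#'   present.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (anyDuplicated(m$id)) abort("manifest error: participant ids must be unique")
  if (!all(m$sex %in% c("female", "male"))) {
    abort("manifest error: sex must be 'female' or 'male'")
  }
  if (all(c("bmi", "height", "weight") %in% names(m))) {
    ok <- is.na(m$bmi) | is.na(m$height) | is.na(m$weight) |
      abs(m$bmi - m$weight / (m$height / 100)^2) <= 0.1
    if (!all(ok)) {
      abort(sprintf("manifest error: bmi inconsistent with height/weight for id '%s'",
                    m$id[which(!ok)[1]]))
    }
  }
  m
}
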