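# Footplate hardware constants. The sensor grid has a 5 mm pitch (25 mm^2
# cells), a 5 kPa amplitude resolution, a 10 kPa detection threshold, and
# samples at 100 Hz. Gravitational acceleration g = 9.8 m/s^2 is the value
# used for body-weight normalization throughout.
SENSOR_PITCH_MM <- 5
SENSOR_AREA_MM2 <- 25
SENSOR_RESOLUTION_KPA <- 5
DETECTION_THRESHOLD_KPA <- 10
SAMPLING_RATE_HZ <- 100
GRAVITY <- 9.8

#' Sensor and standard-grid constants
#'
#' Returns the hardware and coordinate-system constants used throughout the
#' package: sensor pitch (mm), sensor area (mm^2), pressure resolution (kPa),
#' detection threshold (kPa), sampling rate (Hz), gravitational acceleration
#' (m/s^2), and the landmark scale of the standardized foot grid (A.U.).
#'
#' @return A named list of constants.
#' @export
#' @examples
#' sensor_constants()$pitch_mm
sensor_constants <- function() {
  list(
    pitch_mm = SENSOR_PITCH_MM,
    sensor_area_mm2 = SENSOR_AREA_MM2,
    resolution_kpa = SENSOR_RESOLUTION_KPA,
    detection_threshold_kpa = DETECTION_THRESHOLD_KPA,
    rate_hz = SAMPLING_RATE_HZ,
    gravity = GRAVITY,
    landmark_scale_au = 100
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed for a named substream so that independent stages
# (cohort generation, permutations, ...) never share a stream. Kept below
# 2^31 - 1.
substream_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  offs <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

# Normal draws truncated at +/- 3 SD (resampling out-of-range draws).
rnorm_trunc3 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
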