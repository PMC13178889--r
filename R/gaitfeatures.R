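#' Basic gait parameters from two consecutive stances
#'
#' Step length is the progression-axis distance between the heel-contact
#' positions (Landmark 1) of two consecutive stances of opposite feet; step
#' duration is the interval between their onsets; cadence is 60 s divided by
#' the step duration; walking speed is step length over step duration. The
#' foot angle reported is the left/right average.
#'
#' @param stances List of two stance phases ordered by onset, opposite feet.
#' @param lms List of two landmark pairs (global 0-based sensor units)
#'   matching `stances`.
#' @param sides Character vector of two sides (`"left"`/`"right"`).
#' @param rate_hz Sampling rate (Hz).
#' @param pitch_mm Sensor pitch (mm).
#' @return One-row tibble: `step_length` (m), `step_duration` (s),
#'   `cadence` (steps/min), `speed` (m/s), `foot_angle` (deg).
#' @export
basic_gait_params <- function(stances, lms, sides, rate_hz = SAMPLING_RATE_HZ,
                              pitch_mm = SENSOR_PITCH_MM) {
  if (length(stances) != 2 || length(lms) != 2 || length(sides) != 2) {
    abort("exactly two stances, landmark pairs and sides are required")
  }
  if (sides[1] == sides[2]) abort("consecutive stances must be of opposite feet")
  if (stances[[1]]$onset > stances[[2]]$onset) {
    abort("stances must be ordered by onset")
  }
  step_length <- abs(lms[[2]]$L1[1] - lms[[1]]$L1[1]) * pitch_mm / 1000
  step_duration <- (stances[[2]]$onset - stances[[1]]$onset) / rate_hz
  angles <- c(foot_angle(lms[[1]], sides[1]), foot_angle(lms[[2]], sides[2]))
  tibble(
    step_length = step_length,
    step_duration = step_duration,
    cadence = 60 / step_duration,
    speed = step_length / step_duration,
    foot_angle = mean(angles)
  )
}

#' Pressure parameters of a stance phase
#'
#' Contact area counts the sensors activated in *any* frame of the stance
#' (0.25 cm^2 each at 5 mm pitch); peak pressure is the maximum pressure
#' recorded by any sensor in any frame; maximum force is the largest
#' per-frame total load.
#'
#' @param stance A stance phase from [segment_stances()].
#' @param pitch_mm Sensor pitch in mm (defaults to the stance's own pitch).
#' @return One-row tibble: `contact_area` (cm^2), `peak_pressure` (kPa),
#'   `max_force` (N).
#' @export
pressure_params <- function(stance, pitch_mm = stance$pitch_mm) {
  active_any <- apply(stance$frames > 0, c(2, 3), any)
  area_cm2 <- sum(active_any) * pitch_mm^2 / 100
  force <- total_force(stance$frames, cell_area_mm2 = pitch_mm^2)
  tibble(
    contact_area = area_cm2,
    peak_pressure = max(stance$frames),
    max_force = max(force)
  )
}

#' Total-force series of a stance (N)
#'
#' @param stance A stance phase.
#' @return Numeric vector, one value per frame from onset to offset.
#' @export
stance_force_series <- function(stance) {
  total_force(stance$frames, cell_area_mm2 = stance$pitch_mm^2)
}

#' Detect the three peaks of the M-shaped total-force curve
#'
#' The total vertical force during stance typically follows a triphasic
#' ("M-shaped") course: a load-response maximum (Peak 1), a mid-stance
#' minimum (Peak 2, the "valley"), and a push-off maximum (Peak 3). Local
#' maxima are located on a lightly smoothed copy of the series (moving
#' average, window 3) and must be separated by at least 10% of the series
#' length; the valley is the raw-series minimum strictly between the two
#' chosen maxima, and Peaks 1/3 are the raw-series maxima before/after the
#' valley.
#'
#' @param force Non-negative numeric series (length >= 5).
#' @return List with `valid` (logical; `FALSE` when no triphasic structure
#'   is found, e.g. monotone or single-peak series) and, when valid,
#'   0-based indices `peak1 < peak2 < peak3` into `force`.
#' @export
detect_m_peaks <- function(force) {
  n <- length(force)
  if (n < 5) return(list(valid = FALSE))
  sm <- stats::filter(force, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(force[1:2]); sm[n] <- mean(force[(n - 1):n])
  sm <- as.numeric(sm)
  interior <- 2:(n - 1)
  is_max <- vapply(interior, function(i) {
    sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]
  }, logical(1))
  cand <- interior[is_max]
  if (length(cand) < 2) return(list(valid = FALSE))
  min_sep <- max(2, ceiling(0.1 * n))
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  first <- cand[1]
  far <- cand[abs(cand - first) >= min_sep]
  if (length(far) == 0) return(list(valid = FALSE))
  second <- far[1]
  lo <- min(first, second); hi <- max(first, second)
  between <- (lo + 1):(hi - 1)
  p2 <- between[which.min(force[between])]
  p1 <- which.max(force[1:(p2 - 1)])
  p3 <- p2 + which.max(force[(p2 + 1):n])
  if (!(force[p2] < min(force[p1], force[p3]))) return(list(valid = FALSE))
  # sub-frame refinement: a parabola fitted around each extremum averages
  # out frame-level sensor noise; the vertex is rounded back to a frame
  p1r <- refine_extremum(force, p1, 1, p2 - 1)
  p3r <- refine_extremum(force, p3, p2 + 1, n)
  p2r <- refine_extremum(force, p2, p1r + 1, p3r - 1)
  if (p1r < p2r && p2r < p3r && force[p2r] < min(force[p1r], force[p3r])) {
    p1 <- p1r; p2 <- p2r; p3 <- p3r
  }
  list(valid = TRUE, peak1 = p1 - 1L, peak2 = p2 - 1L, peak3 = p3 - 1L)
}

# Quadratic-vertex refinement of a discrete extremum location. Fits a
# parabola to the series on a +/-3 window (clipped to [lo, hi]) and rounds
# the vertex to the nearest frame; the discrete location is kept when the
# fit is degenerate or the vertex strays more than 1.5 frames.
refine_extremum <- function(y, idx, lo, hi, window = 3) {
  xs <- max(lo, idx - window):min(hi, idx + window)
  if (length(xs) < 5) return(idx)
  fit <- stats::lm.fit(cbind(1, xs - idx, (xs - idx)^2), y[xs])
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a == 0) return(idx)
  # a strongly asymmetric (non-parabolic) extremum biases the vertex; keep
  # the discrete argmax when the quadratic lack-of-fit is of the same
  # order as the curvature itself
  if (sqrt(mean(fit$residuals^2)) > 0.95 * abs(a)) return(idx)
  v <- -b / (2 * a)
  if (abs(v) > 1.5) return(idx)
  out <- as.integer(round(idx + v))
  min(max(out, lo), hi)
}

#' Temporal parameters of the M-shaped force curve
#'
#' Divides contact time into four intervals at the three peak timings:
#' onset to Peak 1, Peak 1 to Peak 2 (the valley), Peak 2 to Peak 3, and
#' Peak 3 to offset, in milliseconds and as percentages of total contact
#' time. Transient Phase indices are the midpoints of (Peak 1, Peak 2) and
#' (Peak 2, Peak 3), rounding half toward the earlier frame.
#'
#' @param peaks List with `peak1 < peak2 < peak3` (frame indices on the
#'   same 0-based scale as `onset`/`offset`).
#' @param onset,offset Stance onset/offset frame indices.
#' @param rate_hz Sampling rate (Hz).
#' @return One-row tibble with `peak1..3`, `interval1..4` (ms),
#'   `prop_interval1..4` (%), `transient1`, `transient2`, `contact_ms`.
#' @export
#' @examples
#' temporal_params(list(peak1 = 17, peak2 = 33, peak3 = 50), 0, 66, 100)
temporal_params <- function(peaks, onset, offset, rate_hz = SAMPLING_RATE_HZ) {
  p <- c(peaks$peak1, peaks$peak2, peaks$peak3)
  if (!(onset < p[1] && p[1] < p[2] && p[2] < p[3] && p[3] < offset)) {
    abort("ordering violation: need onset < peak1 < peak2 < peak3 < offset")
  }
  ms <- 1000 / rate_hz
  iv <- c(p[1] - onset, p[2] - p[1], p[3] - p[2], offset - p[3]) * ms
  contact <- (offset - onset) * ms
  tibble(
    peak1 = p[1], peak2 = p[2], peak3 = p[3],
    interval1 = iv[1], interval2 = iv[2], interval3 = iv[3], interval4 = iv[4],
    prop_interval1 = iv[1] / contact * 100,
    prop_interval2 = iv[2] / contact * 100,
    prop_interval3 = iv[3] / contact * 100,
    prop_interval4 = iv[4] / contact * 100,
    transient1 = floor((p[1] + p[2]) / 2),
    transient2 = floor((p[2] + p[3]) / 2),
    contact_ms = contact
  )
}

#' Stance time-series set: force, averaged pressure, contact area, COP
#'
#' Computes per-frame weight-normalized total force (BW%), weight-normalized
#' averaged pressure over activated sensors, contact area (cm^2), and the
#' center of pressure (pressure-weighted mean of the sensor coordinates;
#' `cop_x` mediolateral, `cop_y` progression, in mm), then resamples each
#' series to `n_points` by natural cubic spline over normalized time
#' [0, 1]. Frames inside the stance with no activated sensor have an
#' undefined COP; these are filled by linear interpolation from neighbouring
#' frames and counted in the `n_undefined_cop` attribute.
#'
#' @param stance A stance phase.
#' @param mass Body mass in kg.
#' @param n_points Number of resampled time points (50 by default; 100 for
#'   the high-resolution robustness variant).
#' @param resample If `FALSE`, return the raw per-frame series instead.
#' @return A tibble with columns `time` (normalized), `total_force_bw`,
#'   `avg_pressure`, `contact_area`, `cop_x`, `cop_y`.
#' @export
time_series_set <- function(stance, mass, n_points = 50, resample = TRUE) {
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  fr <- stance$frames
  n_t <- dim(fr)[1]
  pitch <- stance$pitch_mm
  rows_mm <- (stance$row0 + seq_len(dim(fr)[2]) - 1) * pitch
  cols_mm <- (stance$col0 + seq_len(dim(fr)[3]) - 1) * pitch
  force_n <- total_force(fr, cell_area_mm2 = pitch^2)
  d <- dim(fr)
  flat <- matrix(fr, n_t, d[2] * d[3])           # cells column-major (row fastest)
  n_act <- rowSums(flat > 0)
  area <- n_act * pitch^2 / 100
  psum <- rowSums(flat)
  avgp <- ifelse(n_act > 0, psum / n_act, 0)
  ycoord <- rep(rows_mm, times = d[3])
  xcoord <- rep(cols_mm, each = d[2])
  cop_y <- as.vector(flat %*% ycoord) / psum     # NaN when psum == 0
  cop_x <- as.vector(flat %*% xcoord) / psum
  cop_y[psum == 0] <- NA_real_
  cop_x[psum == 0] <- NA_real_
  n_undef <- sum(is.na(cop_x))
  if (n_undef > 0 && n_undef < n_t) {
    ok <- which(!is.na(cop_x))
    cop_x <- approx(ok, cop_x[ok], xout = seq_len(n_t), rule = 2)$y
    cop_y <- approx(ok, cop_y[ok], xout = seq_len(n_t), rule = 2)$y
  }
  bw <- mass * GRAVITY
  raw <- tibble(
    time = if (n_t > 1) (seq_len(n_t) - 1) / (n_t - 1) else 0,
    total_force_bw = force_n / bw * 100,
    avg_pressure = avgp / bw,
    contact_area = area,
    cop_x = cop_x, cop_y = cop_y
  )
  out <- if (!resample) raw else {
    tt <- seq(0, 1, length.out = n_points)
    res <- tibble(time = tt)
    for (nm in setdiff(names(raw), "time")) {
      f <- splinefun(raw$time, raw[[nm]], method = "natural")
      res[[nm]] <- f(tt)
    }
    # force, pressure and area are non-negative quantities; spline
    # overshoot below zero near sharp onsets is clamped
    for (nm in c("total_force_bw", "avg_pressure", "contact_area")) {
      res[[nm]] <- pmax(res[[nm]], 0)
    }
    res
  }
  attr(out, "n_undefined_cop") <- n_undef
  out
}
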