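mk_stance <- function(frames, row0 = 0L, col0 = 0L, pitch = 5, rate = 100) {
  d <- dim(frames)
  list(frames = frames, mask = matrix(TRUE, d[2], d[3]), row0 = row0,
       col0 = col0, onset = 0L, offset = d[1] - 1L, pitch_mm = pitch,
       rate_hz = rate, id = "t")
}

test_that("basic gait parameters follow their defining ratios", {
  fr <- array(0, c(3, 4, 4)); fr[, 2, 2] <- 100
  s1 <- mk_stance(fr); s2 <- mk_stance(fr, row0 = 140L)
  s2$onset <- 50L; s2$offset <- 52L
  lms <- list(list(L1 = c(1, 2), L2 = c(41, 2)),
              list(L1 = c(141, 2), L2 = c(181, 2)))
  g <- basic_gait_params(list(s1, s2), lms, c("left", "right"),
                         rate_hz = 100, pitch_mm = 5)
  expect_equal(g$step_duration, 0.5)
  expect_equal(g$cadence, 120)          # 60 s / 0.5 s
  expect_equal(g$step_length, 0.7)      # 140 rows * 5 mm
  expect_equal(g$speed, 1.4)
  expect_equal(g$cadence, 60 / g$step_duration, tolerance = 1e-9)
  expect_equal(g$speed, g$step_length / g$step_duration, tolerance = 1e-9)
  expect_error(
    basic_gait_params(list(s1, s2), lms, c("left", "left")),
    "opposite")
})

test_that("pressure parameters have their closed forms", {
  # uniform pressure P = 80 kPa over A = 12 sensors, all frames
  fr <- array(0, c(6, 5, 5))
  fr[, 2:4, 2:5] <- 80
  st <- mk_stance(fr)
  pp <- pressure_params(st)
  expect_equal(pp$peak_pressure, 80)
  expect_equal(pp$contact_area, 12 * 0.25)
  expect_equal(pp$max_force, 80 * 1000 * 12 * 25e-6)
  # 400 activated sensors at 5 mm pitch -> 100 cm^2
  fr2 <- array(0, c(2, 20, 20)); fr2[1, , ] <- 50
  expect_equal(pressure_params(mk_stance(fr2))$contact_area, 100)
  # max_force equals the max of the independently computed force series
  co <- generate_stance(default_stance_profile("male"), seed = 6)
  st3 <- mk_stance(co$frames)
  expect_equal(pressure_params(st3)$max_force,
               max(stance_force_series(st3)))
})

test_that("M-peak detection finds constructed extrema and flags degenerate series", {
  f <- c(seq(5, 100, length.out = 11),      # rises to peak at index 10 (0-based)
         seq(100, 60, length.out = 16)[-1], # valley at 25
         seq(60, 105, length.out = 16)[-1], # peak at 40
         seq(105, 5, length.out = 11)[-1])
  pk <- detect_m_peaks(f)
  expect_true(pk$valid)
  expect_equal(c(pk$peak1, pk$peak2, pk$peak3), c(10, 25, 40))
  expect_false(detect_m_peaks(seq_len(30))$valid)
  expect_false(detect_m_peaks(exp(-(1:40 - 20)^2 / 40))$valid)
  expect_false(detect_m_peaks(c(1, 2, 3))$valid)
})

test_that("detected peaks match generator truth within one frame", {
  for (sx in c("female", "male")) {
    for (seed in 1:6) {
      gs <- generate_stance(default_stance_profile(sx), seed = seed)
      pk <- detect_m_peaks(total_force(gs$frames))
      expect_true(pk$valid)
      expect_lte(abs(pk$peak1 - gs$truth$peak1), 1)
      expect_lte(abs(pk$peak2 - gs$truth$peak2), 2)
      expect_lte(abs(pk$peak3 - gs$truth$peak3), 1)
    }
  }
})

test_that("temporal parameters partition contact time", {
  # 1000 Hz so that millisecond timings map to frames directly
  tp <- temporal_params(list(peak1 = 175, peak2 = 335, peak3 = 500),
                        onset = 0, offset = 660, rate_hz = 1000)
  expect_equal(c(tp$interval1, tp$interval2, tp$interval3, tp$interval4),
               c(175, 160, 165, 160))
  expect_equal(tp$contact_ms, 660)
  expect_equal(tp$transient1, 255)   # floor((175 + 335)/2)
  expect_equal(tp$transient2, 417)   # floor((335 + 500)/2), half rounds down
  # at 100 Hz an interval in ms is the frame difference times 10
  tp2 <- temporal_params(list(peak1 = 17, peak2 = 33, peak3 = 50),
                         onset = 0, offset = 66, rate_hz = 100)
  expect_equal(tp2$interval2, (33 - 17) * 10)
  # proportional intervals always sum to 100
  set.seed(8)
  for (i in 1:20) {
    ks <- sort(sample(1:98, 3))
    tp3 <- temporal_params(list(peak1 = ks[1], peak2 = ks[2], peak3 = ks[3]),
                           onset = 0, offset = 99, rate_hz = 100)
    expect_equal(tp3$prop_interval1 + tp3$prop_interval2 +
                   tp3$prop_interval3 + tp3$prop_interval4, 100,
                 tolerance = 1e-9)
    expect_equal(tp3$interval1 + tp3$interval2 + tp3$interval3 + tp3$interval4,
                 tp3$contact_ms, tolerance = 1e-9)
  }
  expect_error(temporal_params(list(peak1 = 5, peak2 = 4, peak3 = 9), 0, 20),
               "ordering")
})

test_that("COP sits at the weighted centre and inside the active bounding box", {
  fr <- array(0, c(3, 6, 6))
  fr[, 2, 2] <- 50; fr[, 4, 6] <- 50   # two equal sensors
  st <- mk_stance(fr)
  ts <- time_series_set(st, mass = 60, resample = FALSE)
  # geometric midpoint, in mm (0-based sensor coords * 5 mm)
  expect_equal(ts$cop_y[1], mean(c(1, 3)) * 5)
  expect_equal(ts$cop_x[1], mean(c(1, 5)) * 5)
  # per-frame COP within the bounding box of that frame's active sensors
  gs <- generate_stance(default_stance_profile("female"), seed = 12)
  st2 <- mk_stance(gs$frames)
  raw <- time_series_set(st2, mass = 55, resample = FALSE)
  d <- dim(gs$frames)
  for (t in seq_len(d[1])) {
    p <- matrix(gs$frames[t, , ], d[2], d[3])
    act <- which(p > 0, arr.ind = TRUE)
    expect_gte(raw$cop_y[t], (min(act[, 1]) - 1) * 5)
    expect_lte(raw$cop_y[t], (max(act[, 1]) - 1) * 5)
    expect_gte(raw$cop_x[t], (min(act[, 2]) - 1) * 5)
    expect_lte(raw$cop_x[t], (max(act[, 2]) - 1) * 5)
  }
})

test_that("time normalization preserves constants and the force identity holds", {
  fr <- array(0, c(9, 4, 4)); fr[, 2, 2] <- 200
  st <- mk_stance(fr)
  ts <- time_series_set(st, mass = 65, n_points = 50)
  expect_equal(nrow(ts), 50)
  expect_true(all(abs(ts$total_force_bw - ts$total_force_bw[1]) < 1e-9))
  expect_true(all(abs(ts$contact_area - 0.25) < 1e-9))
  # averaged pressure * active count * sensor area = total force per frame
  gs <- generate_stance(default_stance_profile("female"), seed = 3)
  st2 <- mk_stance(gs$frames)
  raw <- time_series_set(st2, mass = 55, resample = FALSE)
  force <- stance_force_series(st2)
  n_act <- raw$contact_area * 100 / 25
  lhs <- raw$avg_pressure * (55 * 9.8) * n_act * 25e-6 * 1000
  expect_equal(lhs, force, tolerance = 1e-6)
})

test_that("frames without activation get an interpolated, flagged COP", {
  fr <- array(0, c(5, 4, 4))
  fr[c(1, 2, 4, 5), 2, 2] <- 100    # frame 3 silent
  fr[c(1, 2, 4, 5), 2, 3] <- 100
  st <- mk_stance(fr)
  st$frames[3, , ] <- 0
  raw <- time_series_set(st, mass = 60, resample = FALSE)
  expect_equal(attr(raw, "n_undefined_cop"), 1)
  expect_false(anyNA(raw$cop_x))
})
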