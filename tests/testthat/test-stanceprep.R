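test_that("segmentation finds nothing in an all-zero recording", {
  rec <- pressure_recording(array(0, c(5, 6, 6)))
  expect_equal(segment_stances(rec), list())
})

test_that("segmentation recovers onset/offset and footprint support exactly", {
  rec <- block_recording(list(
    list(t = 4:18, rows = 2:5, cols = 2:4, value = 50),
    list(t = 10:17, rows = 8:11, cols = 6:9, value = 80)
  ), T = 20, H = 12, W = 10)
  st <- segment_stances(rec, min_sensors = 2)
  expect_length(st, 2)
  # 0-based frame indices: active frames 4..18 (1-based) -> onset 3, offset 17
  expect_equal(st[[1]]$onset, 3L)
  expect_equal(st[[1]]$offset, 17L)
  expect_equal(st[[2]]$onset, 9L)
  expect_equal(st[[2]]$offset, 16L)
  # union of active supports reproduces the original non-zero support
  support <- matrix(FALSE, 12, 10)
  for (s in st) {
    sub <- matrix(colSums(matrix(s$frames, dim(s$frames)[1], length(s$mask))) > 0,
                  nrow(s$mask), ncol(s$mask))
    support[s$row0 + seq_len(nrow(s$mask)), s$col0 + seq_len(ncol(s$mask))] <-
      support[s$row0 + seq_len(nrow(s$mask)), s$col0 + seq_len(ncol(s$mask))] | sub
  }
  orig <- matrix(colSums(matrix(rec$frames, 20, 120) > 0) > 0, 12, 10)
  expect_identical(support, orig)
})

test_that("segmentation matches generator stance truth", {
  co <- generate_cohort(tiny_synth_config(seed = 5))
  pt <- participant_recording(co, 1)
  st <- segment_stances(pt$recording)
  expect_length(st, 2)
  sides <- c(pt$truth[[1]]$side, pt$truth[[2]]$side)
  for (k in 1:2) {
    expect_lte(abs(st[[k]]$onset - pt$truth[[k]]$onset), 1)
    expect_lte(abs(st[[k]]$offset - pt$truth[[k]]$offset), 1)
  }
})

test_that("foot angle follows the external-rotation sign convention", {
  expect_equal(foot_angle(list(L1 = c(0, 0), L2 = c(48, 0)), "right"), 0)
  # constructed 10-degree external rotation of a right foot
  theta <- 10 * pi / 180
  lm_r <- list(L1 = c(2, 5), L2 = c(2, 5) + 40 * c(cos(theta), sin(theta)))
  expect_equal(foot_angle(lm_r, "right"), 10, tolerance = 1e-9)
  # mirror-image left foot has the same (positive) angle
  lm_l <- list(L1 = c(2, 5), L2 = c(2, 5) + 40 * c(cos(theta), -sin(theta)))
  expect_equal(foot_angle(lm_l, "left"), foot_angle(lm_r, "right"),
               tolerance = 1e-9)
  expect_error(foot_angle(list(L1 = c(1, 1), L2 = c(1, 1)), "right"),
               "coincide")
})

test_that("standardization scales landmarks to 100 A.U. and is near-identity on aligned input", {
  # a foot already in standard pose: L1 at (10, 29.5), axis along rows,
  # landmark distance 100 sensor units -> transform is the identity on the
  # grid nodes, so bilinear resampling reproduces the input
  H <- 120; W <- 60
  Y <- matrix(0:(H - 1), H, W)
  X <- matrix(seq(-29.5, 29.5, by = 1), H, W, byrow = TRUE)
  blob <- 200 * exp(-((Y - 60)^2 / 1600 + X^2 / 100))
  blob[blob < 10] <- 0
  fr <- array(0, c(1, H, W)); fr[1, , ] <- blob
  rec <- pressure_recording(fr, pitch_mm = 5)
  st <- segment_stances(rec)[[1]]
  lm <- list(L1 = c(10, 29.5), L2 = c(110, 29.5))
  sf <- standardize_foot(st, lm)
  d <- sf$landmarks_std[2, ] - sf$landmarks_std[1, ]
  expect_equal(sqrt(sum(d^2)), 100, tolerance = 1e-6)
  # direction parallel to the progression axis
  expect_equal(unname(d[2]), 0, tolerance = 1e-9)
  expect_equal(max(abs(sf$grid[1, , ] - blob)), 0, tolerance = 1e-8)
})

test_that("landmark distance is 100 and total force conserved for rotated synthetic feet", {
  for (ang in c(-6, 3, 12)) {
    pr <- default_stance_profile("female")
    pr$foot_angle <- ang
    gs <- generate_stance(pr, seed = 30 + ang)
    rec <- pressure_recording(gs$frames, threshold = FALSE)
    st <- segment_stances(rec)[[1]]
    lm <- list(L1 = gs$truth$landmarks$L1 - c(gs$row0, gs$col0),
               L2 = gs$truth$landmarks$L2 - c(gs$row0, gs$col0))
    mid <- floor(dim(st$frames)[1] / 2)
    sf <- standardize_foot(st, lm, frames = mid)
    d <- sf$landmarks_std[2, ] - sf$landmarks_std[1, ]
    expect_equal(sqrt(sum(d^2)), 100, tolerance = 1e-6)
    f_before <- stance_force_series(st)[mid + 1]
    f_after <- sum(sf$grid[1, , ]) * 1000 * sf$cell_area_mm2 * 1e-6
    expect_lt(abs(f_after - f_before) / f_before, 0.02)
  }
})

test_that("standardization is idempotent up to interpolation tolerance", {
  pr <- default_stance_profile("female")
  pr$foot_angle <- 7
  gs <- generate_stance(pr, seed = 4)
  rec <- pressure_recording(gs$frames, threshold = FALSE)
  st <- segment_stances(rec)[[1]]
  lm <- list(L1 = gs$truth$landmarks$L1 - c(gs$row0, gs$col0),
             L2 = gs$truth$landmarks$L2 - c(gs$row0, gs$col0))
  mid <- floor(dim(st$frames)[1] / 2)
  sf1 <- standardize_foot(st, lm, frames = mid)
  # re-wrap the standardized map as a stance on a 1-unit grid and
  # standardize again with the standard landmarks
  m <- sf1$grid[1, , ]
  st2 <- list(frames = array(m, c(1, nrow(m), ncol(m))),
              mask = m >= 0, row0 = 0L, col0 = 0L, onset = 0L, offset = 0L,
              pitch_mm = 1, rate_hz = 100, id = "std")
  sf2 <- standardize_foot(st2, list(L1 = c(10, 29.5), L2 = c(110, 29.5)))
  active <- m > 20
  expect_lt(max(abs(sf2$grid[1, , ][active] - m[active])) / max(m), 0.08)
})

test_that("weight normalization follows force = mass * g", {
  expect_equal(weight_normalize(637, 65, as_bw_percent = TRUE), 100)
  expect_equal(weight_normalize(matrix(0, 2, 2), 70), matrix(0, 2, 2))
  m <- matrix(runif(9, 0, 100), 3, 3)
  expect_equal(weight_normalize(m, 120), weight_normalize(m, 60) / 2)
  expect_error(weight_normalize(m, 0), "mass")
})
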