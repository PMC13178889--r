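#' Segment stance phases from a recording
#'
#' Identifies spatially distinct footprints by 8-connected component
#' analysis of the time-collapsed activation map (any sensor ever active),
#' then finds each footprint's temporal extent: the onset is the first frame
#' in which any sensor within the footprint region records a non-zero
#' pressure, the offset is the last such frame.
#'
#' @param rec A `pressure_recording`.
#' @param min_sensors Components with fewer active sensors are discarded as
#'   debris (default 5).
#' @return A list of stance phases ordered by onset. Each stance is a list
#'   with `onset`/`offset` (0-based frame indices), `frames` (sub-stack
#'   cropped to the footprint bounding box, pressures outside the footprint
#'   region zeroed), `row0`/`col0` (0-based sensor coordinates of the
#'   bounding-box origin), `mask` (footprint region within the box),
#'   `pitch_mm`, `rate_hz`, and `id`. An all-zero recording yields an empty
#'   list.
#' @export
segment_stances <- function(rec, min_sensors = 5) {
  if (!inherits(rec, "pressure_recording")) abort("`rec` must be a pressure_recording.")
  fr <- rec$frames
  d <- dim(fr)
  flat <- matrix(fr, d[1], d[2] * d[3])
  collapsed <- matrix(colSums(flat > 0) > 0, d[2], d[3])
  lab <- label_components(collapsed)
  ks <- setdiff(sort(unique(as.vector(lab))), 0L)
  stances <- list()
  for (k in ks) {
    mask_full <- lab == k
    if (sum(mask_full) < min_sensors) next
    rows <- range(which(apply(mask_full, 1, any)))
    cols <- range(which(apply(mask_full, 2, any)))
    mask <- mask_full[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    sub <- fr[, rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    # zero out pressure belonging to other footprints inside this box
    ds <- dim(sub)
    subm <- matrix(sub, ds[1], ds[2] * ds[3])
    subm <- subm * rep(as.numeric(mask), each = ds[1])
    sub <- array(subm, ds)
    active_t <- which(rowSums(subm > 0) > 0)
    if (length(active_t) == 0) next
    stances[[length(stances) + 1]] <- list(
      onset = min(active_t) - 1L, offset = max(active_t) - 1L,
      frames = sub[min(active_t):max(active_t), , , drop = FALSE],
      row0 = rows[1] - 1L, col0 = cols[1] - 1L, mask = mask,
      pitch_mm = rec$pitch_mm, rate_hz = rec$rate_hz, id = rec$id
    )
  }
  stances[order(vapply(stances, `[[`, numeric(1), "onset"))]
}

#' Foot angle from heel and second-toe landmarks
#'
#' The angle between the foot axis (Landmark 1, most posterior heel point,
#' to Landmark 2, tip of the second toe) and the walking-progression axis,
#' in degrees, signed so that external rotation (lateral deviation of the
#' toes) is positive for both feet. Columns are taken to increase toward
#' the walker's right, so the raw angle `atan2(dcol, drow)` is positive
#' toward the right; its sign is flipped for left feet.
#'
#' @param lm A landmark pair: list with `L1` and `L2`, each `c(row, col)` in
#'   sensor units.
#' @param side `"left"` or `"right"`.
#' @return Angle in degrees (external rotation positive).
#' @export
#' @examples
#' foot_angle(list(L1 = c(0, 0), L2 = c(48, 0)), "right")  # aligned: 0
foot_angle <- function(lm, side = c("right", "left")) {
  side <- match.arg(side)
  d <- lm$L2 - lm$L1
  if (all(d == 0)) abort("landmarks L1 and L2 must not coincide")
  theta <- atan2(d[2], d[1]) * 180 / pi
  if (side == "left") -theta else theta
}

# Similarity transform defined by a landmark pair: maps sensor coordinates
# (row, col) to standard foot coordinates (y, x) with L1 at (10, 0), L2 at
# (110, 0). Proper rotation + uniform scaling; `mirror` additionally flips
# the mediolateral axis (used for left feet so medial/lateral align with
# the right-foot template).
landmark_transform <- function(lm, mirror = FALSE) {
  d <- lm$L2 - lm$L1
  len <- sqrt(sum(d^2))
  if (len == 0) abort("landmarks L1 and L2 must not coincide")
  u <- d / len                 # unit vector along the foot axis
  v <- c(-u[2], u[1])          # left-handed perpendicular
  s <- 100 / len               # sensor units -> A.U.
  fwd <- function(p) {         # p: n x 2 matrix of (row, col)
    rel <- sweep(p, 2, lm$L1)
    a <- (rel %*% u) * s
    b <- (rel %*% v) * s
    if (mirror) b <- -b
    cbind(y = a + 10, x = b)
  }
  inv <- function(q) {         # q: n x 2 matrix of (y, x) in A.U.
    a <- (q[, 1] - 10) / s
    b <- q[, 2] / s
    if (mirror) b <- -b
    cbind(lm$L1[1] + a * u[1] + b * v[1],
          lm$L1[2] + a * u[2] + b * v[2])
  }
  list(forward = fwd, inverse = inv, scale_au_per_sensor = s, length_sensor = len)
}

#' Standardize a stance onto the foot coordinate grid
#'
#' Rotates the pressure data around Landmark 1 so that the L1-L2 foot axis
#' aligns with the progression axis, scales uniformly so the landmark
#' distance is 100 A.U., and resamples pressures onto the fixed standard
#' grid by bilinear interpolation (0 outside the source support). The same
#' transform is applied to every frame of the stance.
#'
#' @param stance A stance phase from [segment_stances()].
#' @param lm Landmark pair (`L1`, `L2` in 0-based global sensor units).
#' @param grid Target grid from [standard_grid()].
#' @param mirror Mirror the mediolateral axis (recommended for left feet
#'   when pooling across sides).
#' @param frames `"all"`, or a vector of 0-based frame indices *relative to
#'   the stance onset* to standardize (e.g. peak timings).
#' @return An object of class `standardized_foot`: list with `grid`
#'   (`n x H' x W'` array, kPa), `frame_index` (0-based, stance-relative),
#'   `spec` (the grid), `cell_area_mm2` (physical area of one standard cell
#'   for this foot), `landmarks_std` (transformed landmarks; their distance
#'   is 100 by construction), `weight_normalized` (FALSE), `mirror`.
#' @export
standardize_foot <- function(stance, lm, grid = standard_grid(),
                             mirror = FALSE, frames = "all") {
  H <- nrow(stance$mask); W <- ncol(stance$mask)
  lml <- list(L1 = lm$L1 - c(stance$row0, stance$col0),
              L2 = lm$L2 - c(stance$row0, stance$col0))
  # landmarks may sit slightly outside the contact support (the second-toe
  # tip need not touch the ground), hence the generous pad
  pad <- 12
  if (any(lml$L1 < -pad) || any(lml$L2 < -pad) ||
      lml$L1[1] > H - 1 + pad || lml$L1[2] > W - 1 + pad ||
      lml$L2[1] > H - 1 + pad || lml$L2[2] > W - 1 + pad) {
    abort("landmarks fall outside the stance bounding region")
  }
  tr <- landmark_transform(lml, mirror = mirror)
  nodes <- cbind(rep(grid$y, times = grid$dim[2]),
                 rep(grid$x, each = grid$dim[1]))
  src <- tr$inverse(nodes)     # (row, col) sensor coords, bbox-local
  n_t <- dim(stance$frames)[1]
  if (identical(frames, "all")) {
    idx <- seq_len(n_t) - 1L
  } else {
    idx <- as.integer(frames)
    if (any(idx < 0 | idx >= n_t)) abort("`frames` out of the stance range")
  }
  out <- array(0, c(length(idx), grid$dim[1], grid$dim[2]))
  for (i in seq_along(idx)) {
    Z <- matrix(stance$frames[idx[i] + 1L, , ], H, W)
    vals <- pracma::interp2(x = 0:(W - 1), y = 0:(H - 1), Z = Z,
                            xp = src[, 2], yp = src[, 1], method = "linear")
    vals[is.na(vals)] <- 0
    vals[vals < 0] <- 0
    out[i, , ] <- matrix(vals, grid$dim[1], grid$dim[2])
  }
  lm_std <- tr$forward(rbind(lml$L1, lml$L2))
  cell_mm <- stance$pitch_mm / tr$scale_au_per_sensor  # mm per 1 A.U.
  structure(list(
    grid = out, frame_index = idx, spec = grid,
    cell_area_mm2 = (cell_mm * grid$sy) * (cell_mm * grid$sx),
    landmarks_std = lm_std, weight_normalized = FALSE, mirror = mirror,
    id = stance$id
  ), class = "standardized_foot")
}

#' Normalize pressures or forces by body weight
#'
#' Divides pressure values by body weight (`mass * g`, g = 9.8 m/s^2),
#' giving weight-normalized pressure (kPa/N); force series can instead be
#' expressed as a percentage of body weight via `as_bw_percent`.
#'
#' @param values Pressure map/array (kPa) or force series (N).
#' @param mass Body mass in kg (> 0).
#' @param as_bw_percent If `TRUE`, treat `values` as forces in newtons and
#'   return `force / (mass * g) * 100` (BW%).
#' @return Normalized values with the same shape.
#' @export
#' @examples
#' weight_normalize(637, 65, as_bw_percent = TRUE)  # 100 BW%
weight_normalize <- function(values, mass, as_bw_percent = FALSE) {
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  bw <- mass * GRAVITY
  if (as_bw_percent) values / bw * 100 else values / bw
}
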