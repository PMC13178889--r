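#' Synthetic cohort configuration
#'
#' Generative specification for a two-group (female/male) synthetic plantar
#' pressure cohort with known ground truth. The defaults encode the study
#' conditions the package targets: 68 female and 24 male walkers;
#' per-sex anthropometric distributions (age, height, weight; BMI derived);
#' per-sex step duration, step length and foot angle; per-sex proportional
#' interval means and SDs of the M-shaped total-force curve (summing to 100);
#' per-sex contact time and peak total force in BW%. Anthropometrics and
#' gait parameters are drawn from normal distributions truncated at
#' +/- 3 SD.
#'
#' @param n_female,n_male Group sizes (>= 2 each).
#' @param anthro Per-sex list of `c(mean, sd)` for `age` (yrs), `height`
#'   (cm), `weight` (kg).
#' @param gait Per-sex list of `c(mean, sd)` for `step_duration` (s),
#'   `step_length` (m), `foot_angle` (deg).
#' @param prop_intervals Per-sex list: `mean` (4 percentages summing to
#'   100), `sd` (4 SDs).
#' @param contact_ms Per-sex `c(mean, sd)` of contact time (ms).
#' @param peak_force_bw Per-sex `c(mean, sd)` of peak total force (BW%).
#' @param valley_force_bw `c(mean, sd)` of the mid-stance valley (BW%).
#' @param end_force_bw Total force at stance onset/offset (BW%).
#' @param foot_length_factor Landmark-1-to-second-toe distance as mm per cm
#'   of height.
#' @param step_width_mm Mediolateral separation of the two feet.
#' @param noise_sd_sensor SD of the per-sensor, per-frame multiplicative
#'   log-normal noise.
#' @param noise_sd_subject SD of the subject-level random amplitude.
#' @param regional_effects List of injected group effects, each
#'   `list(region =, delta =, group =)` with `region` a preset name (or
#'   logical mask on the standard grid), `delta` a weight-normalized
#'   pressure offset (kPa/N) and `group` `"female"` or `"male"`.
#' @param pitch_mm,rate_hz Sensor constants.
#' @param seed Integer master seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    n_female = 68, n_male = 24,
    anthro = list(
      female = list(age = c(34.5, 14.9), height = c(159.4, 4.8),
                    weight = c(54.9, 7.3)),
      male = list(age = c(33.7, 14.4), height = c(172.8, 4.9),
                  weight = c(70.1, 9.1))),
    gait = list(
      female = list(step_duration = c(0.490, 0.030),
                    step_length = c(0.702, 0.060),
                    foot_angle = c(3.04, 4.37)),
      male = list(step_duration = c(0.524, 0.048),
                  step_length = c(0.724, 0.063),
                  foot_angle = c(6.35, 3.73))),
    prop_intervals = list(
      female = list(mean = c(26.4, 24.0, 24.8, 24.9),
                    sd = c(3.1, 2.9, 3.6, 2.7)),
      male = list(mean = c(24.3, 20.7, 28.9, 26.1),
                  sd = c(3.1, 4.4, 6.9, 2.2))),
    contact_ms = list(female = c(671, 50), male = c(720, 60)),
    peak_force_bw = list(female = c(121.3, 8), male = c(123.4, 8)),
    valley_force_bw = c(75, 6),
    end_force_bw = 5,
    foot_length_factor = 1.5,
    step_width_mm = 90,
    noise_sd_sensor = 0.12,
    noise_sd_subject = 0.08,
    regional_effects = list(),
    pitch_mm = SENSOR_PITCH_MM, rate_hz = SAMPLING_RATE_HZ,
    seed = 1L) {
  if (n_female < 2 || n_male < 2) abort("need at least 2 participants per group")
  for (sx in c("female", "male")) {
    s <- sum(prop_intervals[[sx]]$mean)
    # printed group means carry rounding; accept it, then renormalize so
    # the generative proportions sum to exactly 100
    if (abs(s - 100) > 0.25) {
      abort(sprintf("proportional intervals for %s sum to %g, not 100", sx, s))
    }
    prop_intervals[[sx]]$mean <- prop_intervals[[sx]]$mean / s * 100
  }
  if (noise_sd_sensor < 0 || noise_sd_subject < 0) abort("noise SDs must be >= 0")
  for (ef in regional_effects) {
    if (!is.finite(ef$delta)) abort("effect magnitudes must be finite")
  }
  structure(list(
    n_female = n_female, n_male = n_male, anthro = anthro, gait = gait,
    prop_intervals = prop_intervals, contact_ms = contact_ms,
    peak_force_bw = peak_force_bw, valley_force_bw = valley_force_bw,
    end_force_bw = end_force_bw, foot_length_factor = foot_length_factor,
    step_width_mm = step_width_mm, noise_sd_sensor = noise_sd_sensor,
    noise_sd_subject = noise_sd_subject, regional_effects = regional_effects,
    pitch_mm = pitch_mm, rate_hz = rate_hz, seed = seed
  ), class = "synth_config")
}

# Piecewise half-cosine total-force waveform through (0, e), (tau1, A1),
# (tau2, A2), (tau3, A3), (1, e): C1-smooth, monotone between knots, with
# extrema exactly at the knots and non-degenerate curvature there.
force_waveform <- function(tau_knots, bw_knots) {
  function(tau) {
    out <- numeric(length(tau))
    for (k in seq_len(length(tau_knots) - 1)) {
      t0 <- tau_knots[k]; t1 <- tau_knots[k + 1]
      v0 <- bw_knots[k]; v1 <- bw_knots[k + 1]
      inseg <- tau >= t0 & (if (k == length(tau_knots) - 1) tau <= t1 else tau < t1)
      u <- (tau[inseg] - t0) / (t1 - t0)
      out[inseg] <- v0 + (v1 - v0) * (1 - cos(pi * u)) / 2
    }
    out
  }
}

#' Default single-stance generation profile
#'
#' @param sex "female" or "male"; fills sex-typical defaults from
#'   [synth_config()].
#' @param config A `synth_config` supplying the population values.
#' @param side,l1_row,l1_col Placement of the foot (Landmark 1, 0-based
#'   global sensor units).
#' @return A named list understood by [generate_stance()].
#' @export
default_stance_profile <- function(sex = "female", config = synth_config(),
                                   side = "right", l1_row = 8, l1_col = 20) {
  list(
    side = side, sex = sex,
    mass_kg = config$anthro[[sex]]$weight[1],
    foot_length_mm = config$foot_length_factor * config$anthro[[sex]]$height[1],
    contact_ms = config$contact_ms[[sex]][1],
    prop_intervals = config$prop_intervals[[sex]]$mean,
    peak_force_bw = config$peak_force_bw[[sex]][1],
    valley_force_bw = config$valley_force_bw[1],
    end_force_bw = config$end_force_bw,
    foot_angle = config$gait[[sex]]$foot_angle[1],
    l1_row = l1_row, l1_col = l1_col,
    pitch_mm = config$pitch_mm, rate_hz = config$rate_hz,
    noise_sd_sensor = config$noise_sd_sensor,
    amp = 1,
    effects = config$regional_effects
  )
}

resolve_effect_mask <- function(region) {
  if (is.character(region)) {
    p <- region_params()[[region]]
    if (is.null(p)) abort(sprintf("unknown region preset '%s'", region))
    function(y, x) ((y - p$cy) / p$ry)^2 + ((x - p$cx) / p$rx)^2 <= 1
  } else if (is.function(region)) {
    region
  } else {
    abort("effect region must be a preset name or a mask function of (y, x)")
  }
}

#' Generate one synthetic stance phase
#'
#' Emits the frames of a single foot contact on a snug local sensor grid.
#' The total-force time course is triphasic by construction (half-cosine
#' arcs between onset, Peak 1, the valley, Peak 3, and offset, at the
#' configured proportional intervals and amplitudes). Spatially, the load
#' is a smooth footprint mixture (heel, lateral midfoot, forefoot) whose
#' heel-to-forefoot weighting shifts over the stance so the centre of
#' pressure progresses forward. Per-sensor multiplicative log-normal noise
#' is applied, pressures are quantized to the 5 kPa device resolution and
#' thresholded at 10 kPa.
#'
#' @param profile Profile list, see [default_stance_profile()]. Must order
#'   the peaks feasibly (all four proportional intervals positive).
#' @param seed Integer seed (local RNG stream).
#' @return List with `frames` (`T x H x W` kPa, local), `row0`/`col0`
#'   (0-based global origin of the local grid) and `truth`: onset/offset
#'   and peak frame indices (0-based, stance-relative), landmark
#'   coordinates (global sensor units), side, and the generating waveform
#'   knots.
#' @export
generate_stance <- function(profile, seed = NULL) {
  pr <- profile
  if (any(pr$prop_intervals <= 0)) {
    abort("infeasible timing: proportional intervals must all be positive")
  }
  if (abs(sum(pr$prop_intervals) - 100) > 0.25) {
    abort("proportional intervals must sum to 100")
  }
  pr$prop_intervals <- pr$prop_intervals / sum(pr$prop_intervals) * 100
  with_seed(seed, {
    n <- max(round(pr$contact_ms / 1000 * pr$rate_hz), 12) + 1
    cum <- cumsum(pr$prop_intervals)[1:3] / 100
    i_pk <- round(cum * (n - 1))          # 0-based truth peak frames
    if (any(diff(c(0, i_pk, n - 1)) < 1)) {
      abort("infeasible timing: peaks collapse onto each other at this rate")
    }
    tau_knots <- c(0, i_pk / (n - 1), 1)
    bw_knots <- c(pr$end_force_bw, pr$peak_force_bw, pr$valley_force_bw,
                  pr$peak_force_bw, pr$end_force_bw)
    fw <- force_waveform(tau_knots, bw_knots)
    tau <- (seq_len(n) - 1) / (n - 1)
    F_bw <- fw(tau)
    F_N <- F_bw / 100 * pr$mass_kg * GRAVITY

    theta <- pr$foot_angle * pi / 180
    sgn <- if (pr$side == "right") 1 else -1
    u <- c(cos(theta), sgn * sin(theta))   # foot axis, sensor units
    v <- c(-u[2], u[1])
    L1 <- c(pr$l1_row, pr$l1_col)
    len_sensor <- pr$foot_length_mm / pr$pitch_mm
    s_au <- len_sensor / 100               # sensors per A.U.
    L2 <- L1 + u * len_sensor
    mirror <- pr$side == "left"

    # local grid bounding the standard-box corners
    bb <- foot_bbox(L1, pr$foot_length_mm, pr$pitch_mm, pr$foot_angle, pr$side)
    r0 <- bb[1]; c0 <- bb[2]; r1 <- bb[3]; c1 <- bb[4]
    b_sgn <- if (mirror) -1 else 1
    H <- r1 - r0 + 1; W <- c1 - c0 + 1
    rr <- rep(r0:r1, times = W); cc <- rep(c0:c1, each = H)
    d1 <- rr - L1[1]; d2 <- cc - L1[2]
    a <- (d1 * u[1] + d2 * u[2]) / s_au
    b <- (d1 * v[1] + d2 * v[2]) / s_au
    y_std <- 10 + a
    x_std <- b_sgn * b                      # right-foot-convention x

    cell_m2 <- (pr$pitch_mm / 1000)^2
    zones <- lapply(c("heel", "midfoot", "forefoot"), function(z) {
      g <- eval_zone(y_std, x_std, z)
      g[g < 1e-4 * max(g)] <- 0
      g / (sum(g) * cell_m2)               # unit integral: 1/m^2
    })

    # temporal zone weights: heel -> forefoot transfer across the stance
    tau2 <- tau_knots[3]
    sstep <- 1 / (1 + exp(-(tau - tau2) / 0.07))
    wm <- 0.18 * exp(-((tau - tau2) / 0.12)^2)
    wh <- (1 - sstep)
    wf <- sstep
    wsum <- wh + wm + wf
    Wz <- cbind(wh, wm, wf) / wsum         # n x 3

    Z <- rbind(zones[[1]], zones[[2]], zones[[3]])  # 3 x (H*W)
    base <- (Wz %*% Z) * F_N               # n x (H*W), pressure in Pa
    base <- base / 1000                    # kPa

    if (length(pr$effects) > 0) {
      bwN <- pr$mass_kg * GRAVITY
      for (ef in pr$effects) {
        maskf <- resolve_effect_mask(ef$region)
        m <- maskf(y_std, x_std)
        if (any(m)) {
          delta_kpa <- ef$delta * bwN
          base <- base + outer(F_bw / max(F_bw), as.numeric(m) * delta_kpa)
        }
      }
    }

    base <- base * pr$amp
    if (pr$noise_sd_sensor > 0) {
      sdl <- pr$noise_sd_sensor
      noise <- matrix(exp(stats::rnorm(length(base), -sdl^2 / 2, sdl)),
                      nrow(base), ncol(base))
      base <- base * noise
    }
    base <- round(base / SENSOR_RESOLUTION_KPA) * SENSOR_RESOLUTION_KPA
    base[base < DETECTION_THRESHOLD_KPA] <- 0

    # base is frames x cells with cells ordered row-fastest, matching the
    # column-major layout of a T x H x W array
    frames <- array(base, c(n, H, W))
    list(
      frames = frames, row0 = r0, col0 = c0,
      truth = list(
        onset = 0L, offset = n - 1L,
        peak1 = i_pk[1], peak2 = i_pk[2], peak3 = i_pk[3],
        landmarks = list(L1 = L1, L2 = L2),
        side = pr$side, tau_knots = tau_knots, bw_knots = bw_knots,
        contact_frames = n
      )
    )
  })
}

#' Inject a regional effect into a standardized pressure template
#'
#' Adds `delta` to every pixel inside the region mask; pixels outside are
#' untouched, so the mean inside the region rises by exactly `delta` (for
#' scalar `delta`).
#'
#' @param template Pressure matrix on a standard grid.
#' @param region Preset name (`"calcaneus"`, `"second_metatarsal"`), or a
#'   logical mask of the same shape as `template`.
#' @param delta Scalar pressure offset, or a matrix of per-pixel offsets
#'   matching `template`.
#' @param grid The grid `template` lives on (used for presets).
#' @return The modified template.
#' @export
inject_regional_effect <- function(template, region, delta,
                                   grid = standard_grid(nrow(template),
                                                        ncol(template))) {
  mask <- if (is.character(region)) region_preset(region, grid) else region
  if (!identical(dim(mask), dim(template))) {
    abort("region mask shape does not match the template")
  }
  if (is.matrix(delta)) {
    if (!identical(dim(delta), dim(template))) {
      abort("per-pixel delta shape does not match the template")
    }
    template[mask] <- template[mask] + delta[mask]
  } else {
    template[mask] <- template[mask] + delta
  }
  template
}

#' Generate subject-level standardized pressure maps
#'
#' Direct generator of weight-normalized pressure maps on a standard grid
#' (the quantity entering spatial cluster testing), bypassing the
#' raw-recording stage. Each subject's map is
#' `template * (1 + eta_subj) * exp(eps_pixel)` on the template support
#' (zero off-support), with `eta_subj ~ N(0, noise_sd_subject)` and
#' log-normal unit-mean pixel noise of SD `noise_sd_sensor`. An optional
#' localized effect is added to group A inside a region preset, either as a
#' uniform offset (`effect_delta`) or scaled to a target pointwise Cohen's
#' d (`effect_d`), using the analytic per-pixel SD
#' `template * sqrt((1 + sd_subj^2) * exp(sd_sensor^2) - 1)`.
#'
#' @param n_a,n_b Subjects per group.
#' @param grid Standard grid (default 40 x 20).
#' @param noise_sd_sensor,noise_sd_subject Noise scales.
#' @param effect_region Preset name or logical mask (`NULL` = no effect).
#' @param effect_d Target pointwise Cohen's d inside the region.
#' @param d_reference How `effect_d` maps to an offset: `"max"` (uniform
#'   delta sized at the region's maximum-template pixel, so d >= the target
#'   everywhere in the region — the way a uniform regional pressure offset
#'   behaves) or `"pixelwise"` (per-pixel delta proportional to the local
#'   SD, exact d at every pixel).
#' @param effect_delta Uniform offset alternative (overrides `effect_d`).
#' @param template_peak Maximum of the weight-normalized template (kPa/N).
#' @param seed Integer seed.
#' @return List with `a`, `b` (subject x pixel matrices carrying a
#'   `map_dim` attribute), `template`, `effect_mask` (logical matrix or
#'   `NULL`), `delta` (per-pixel offsets actually applied), `grid`.
#' @export
generate_pressure_maps <- function(n_a, n_b, grid = standard_grid(40, 20),
                                   noise_sd_sensor = 0.12,
                                   noise_sd_subject = 0.08,
                                   effect_region = NULL, effect_d = 0,
                                   d_reference = c("max", "pixelwise"),
                                   effect_delta = NULL,
                                   template_peak = 1.0, seed = NULL) {
  d_reference <- match.arg(d_reference)
  tpl <- foot_template(grid) * template_peak
  support <- tpl > 0
  npx <- length(tpl)
  mask <- NULL; delta <- NULL
  if (!is.null(effect_region)) {
    mask <- if (is.character(effect_region)) {
      region_preset(effect_region, grid)
    } else effect_region
    mask <- mask & support
    sd_px <- tpl * sqrt((1 + noise_sd_subject^2) * exp(noise_sd_sensor^2) - 1)
    delta <- matrix(0, grid$dim[1], grid$dim[2])
    if (!is.null(effect_delta)) {
      delta[mask] <- effect_delta
    } else if (d_reference == "max") {
      delta[mask] <- effect_d * max(sd_px[mask])
    } else {
      delta[mask] <- effect_d * sd_px[mask]
    }
  }
  gen_group <- function(n, add_effect) {
    base <- matrix(rep(as.vector(tpl), each = n), n, npx)
    if (add_effect && !is.null(delta)) {
      base <- base + matrix(rep(as.vector(delta), each = n), n, npx)
    }
    amp <- 1 + rnorm_trunc3(n, 0, noise_sd_subject)
    base <- base * amp
    eps <- matrix(exp(stats::rnorm(n * npx, -noise_sd_sensor^2 / 2,
                                   noise_sd_sensor)), n, npx)
    out <- base * eps
    out[, !as.vector(support)] <- 0
    attr(out, "map_dim") <- grid$dim
    out
  }
  with_seed(seed, {
    a <- gen_group(n_a, add_effect = TRUE)
    b <- gen_group(n_b, add_effect = FALSE)
    list(a = a, b = b, template = tpl, effect_mask = mask, delta = delta,
         grid = grid)
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws all per-participant parameters (anthropometrics, gait timing,
#' proportional intervals, foot geometry and placement) for the configured
#' two-group cohort and assigns each participant a private seed, making the
#' whole cohort a pure function of `(config, seed)`. Recordings themselves
#' are materialized on demand by [participant_recording()], keeping memory
#' flat; each recording holds one valid trial of two consecutive steps
#' (one per foot).
#'
#' @param config A [synth_config()].
#' @return List of class `synth_cohort`: `manifest` (one tibble row per
#'   participant: demographics, per-foot landmark truth, subject seed) and
#'   `truth` (per-participant generating parameters: step length/duration,
#'   per-foot contact time, proportional intervals, peak BW%, foot
#'   angles), plus `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  n <- config$n_female + config$n_male
  sexes <- rep(c("female", "male"), c(config$n_female, config$n_male))
  with_seed(config$seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sx <- sexes[i]
      an <- config$anthro[[sx]]
      gp <- config$gait[[sx]]
      height <- rnorm_trunc3(1, an$height[1], an$height[2])
      weight <- rnorm_trunc3(1, an$weight[1], an$weight[2])
      age <- rnorm_trunc3(1, an$age[1], an$age[2])
      step_duration <- rnorm_trunc3(1, gp$step_duration[1], gp$step_duration[2])
      step_length <- rnorm_trunc3(1, gp$step_length[1], gp$step_length[2])
      contact <- rnorm_trunc3(1, config$contact_ms[[sx]][1],
                              config$contact_ms[[sx]][2])
      peak_bw <- rnorm_trunc3(1, config$peak_force_bw[[sx]][1],
                              config$peak_force_bw[[sx]][2])
      valley_bw <- rnorm_trunc3(1, config$valley_force_bw[1],
                                config$valley_force_bw[2])
      valley_bw <- min(valley_bw, peak_bw - 15)
      pim <- config$prop_intervals[[sx]]
      props <- pmax(rnorm_trunc3(4, pim$mean, pim$sd), 3)
      props <- props / sum(props) * 100
      angles <- rnorm_trunc3(2, gp$foot_angle[1], gp$foot_angle[2])
      first_side <- sample(c("left", "right"), 1)
      rows[[i]] <- tibble(
        id = sprintf("S%03d", i), sex = sx,
        age = age, height = height, weight = weight,
        bmi = weight / (height / 100)^2,
        step_duration = step_duration, step_length = step_length,
        contact_ms = contact, peak_force_bw = peak_bw,
        valley_force_bw = valley_bw,
        prop1 = props[1], prop2 = props[2], prop3 = props[3],
        prop4 = props[4],
        angle_left = angles[which(c(first_side, other_side(first_side)) == "left")],
        angle_right = angles[which(c(first_side, other_side(first_side)) == "right")],
        first_side = first_side,
        foot_length_mm = config$foot_length_factor * height,
        subject_seed = substream_seed(config$seed, paste0("subject", i))
      )
    }
  })
  manifest <- bind_rows(rows)
  # landmark truth requires the deterministic placement geometry
  lm <- purrr::map(seq_len(n), function(i) {
    geo <- participant_geometry(manifest[i, ], config)
    tibble(
      left_l1_row = geo$left$L1[1], left_l1_col = geo$left$L1[2],
      left_l2_row = geo$left$L2[1], left_l2_col = geo$left$L2[2],
      right_l1_row = geo$right$L1[1], right_l1_col = geo$right$L1[2],
      right_l2_row = geo$right$L2[1], right_l2_col = geo$right$L2[2],
      onset_first = geo$onset1, onset_second = geo$onset2
    )
  }) |> purrr::list_rbind()
  structure(list(manifest = dplyr::bind_cols(manifest, lm), config = config),
            class = "synth_cohort")
}

other_side <- function(s) if (s == "right") "left" else "right"

# Bounding box (0-based global sensor units, c(r0, c0, r1, c1)) of the
# standard-box corners ([0,120] x [-30,30] A.U.) of a placed foot. Shared
# by the stance generator and the cohort geometry so that manifest
# landmarks line up with materialized recordings.
foot_bbox <- function(L1, foot_length_mm, pitch_mm, angle_deg, side) {
  theta <- angle_deg * pi / 180
  sgn <- if (side == "right") 1 else -1
  u <- c(cos(theta), sgn * sin(theta))
  v <- c(-u[2], u[1])
  s_au <- foot_length_mm / pitch_mm / 100
  b_sgn <- if (side == "left") -1 else 1
  corners_au <- rbind(c(0, -30), c(0, 30), c(120, -30), c(120, 30))
  corners <- t(apply(corners_au, 1, function(q) {
    a <- (q[1] - 10) * s_au; b <- b_sgn * q[2] * s_au
    L1 + a * u + b * v
  }))
  c(floor(min(corners[, 1])) - 1, floor(min(corners[, 2])) - 1,
    ceiling(max(corners[, 1])) + 1, ceiling(max(corners[, 2])) + 1)
}

# Deterministic trial geometry for one participant: placement of the two
# consecutive steps, expressed in the coordinate frame of the materialized
# recording (origin at the joint bounding box of both footprints).
participant_geometry <- function(row, config) {
  pitch <- config$pitch_mm
  step_rows <- row$step_length * 1000 / pitch
  width_cols <- config$step_width_mm / pitch
  first <- row$first_side
  second <- other_side(first)
  base_row <- 8; base_col <- 16
  pos <- list()
  pos[[first]] <- c(base_row, if (first == "right") base_col + width_cols else base_col)
  pos[[second]] <- c(base_row + step_rows,
                     if (second == "right") base_col + width_cols else base_col)
  angle <- function(side) if (side == "right") row$angle_right else row$angle_left
  bbs <- lapply(c("left", "right"), function(side) {
    foot_bbox(pos[[side]], row$foot_length_mm, pitch, angle(side), side)
  })
  origin <- c(min(bbs[[1]][1], bbs[[2]][1]), min(bbs[[1]][2], bbs[[2]][2]))
  mk <- function(side) {
    theta <- angle(side) * pi / 180
    sgn <- if (side == "right") 1 else -1
    u <- c(cos(theta), sgn * sin(theta))
    L1 <- pos[[side]] - origin
    list(L1 = L1, L2 = L1 + u * row$foot_length_mm / pitch)
  }
  onset2 <- round(row$step_duration * config$rate_hz)
  list(left = mk("left"), right = mk("right"),
       first = first, second = second,
       onset1 = 0L, onset2 = as.integer(onset2))
}

#' Materialize one participant's recording
#'
#' Deterministically regenerates the two-step pressure recording of a
#' cohort participant from their stored parameters and private seed.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param i Participant row index (or id string).
#' @return A list: `recording` (a `pressure_recording` holding both steps)
#'   and `truth` (per-side stance truth: global onset/offset, peak frames,
#'   landmarks).
#' @export
participant_recording <- function(cohort, i) {
  cfg <- cohort$config
  if (is.character(i)) i <- match(i, cohort$manifest$id)
  row <- cohort$manifest[i, ]
  geo <- participant_geometry(row, cfg)
  mk_profile <- function(side, k) {
    list(
      side = side, sex = row$sex, mass_kg = row$weight,
      foot_length_mm = row$foot_length_mm,
      contact_ms = row$contact_ms,
      prop_intervals = c(row$prop1, row$prop2, row$prop3, row$prop4),
      peak_force_bw = row$peak_force_bw,
      valley_force_bw = row$valley_force_bw,
      end_force_bw = cfg$end_force_bw,
      foot_angle = if (side == "right") row$angle_right else row$angle_left,
      l1_row = geo[[side]]$L1[1], l1_col = geo[[side]]$L1[2],
      pitch_mm = cfg$pitch_mm, rate_hz = cfg$rate_hz,
      noise_sd_sensor = cfg$noise_sd_sensor,
      amp = 1,
      effects = Filter(function(ef) is.null(ef$group) || ef$group == row$sex,
                       cfg$regional_effects)
    )
  }
  amp_subj <- with_seed(substream_seed(row$subject_seed, "amp"),
                        1 + rnorm_trunc3(1, 0, cfg$noise_sd_subject))
  sides <- c(geo$first, geo$second)
  onsets <- c(geo$onset1, geo$onset2)
  st <- purrr::map(1:2, function(k) {
    pr <- mk_profile(sides[k], k)
    pr$amp <- amp_subj
    generate_stance(pr, seed = substream_seed(row$subject_seed, sides[k]))
  })
  # assemble the recording; geometry is already in recording coordinates,
  # so the joint bounding box of both footprints starts at (0, 0)
  r_max <- max(vapply(st, function(s) s$row0 + dim(s$frames)[2] - 1, numeric(1)))
  c_max <- max(vapply(st, function(s) s$col0 + dim(s$frames)[3] - 1, numeric(1)))
  T_tot <- max(onsets + vapply(st, function(s) dim(s$frames)[1], numeric(1)))
  frames <- array(0, c(T_tot, r_max + 1, c_max + 1))
  for (k in 1:2) {
    d <- dim(st[[k]]$frames)
    rs <- (st[[k]]$row0 + 1):(st[[k]]$row0 + d[2])
    cs <- (st[[k]]$col0 + 1):(st[[k]]$col0 + d[3])
    ts <- (onsets[k] + 1):(onsets[k] + d[1])
    frames[ts, rs, cs] <- frames[ts, rs, cs] + st[[k]]$frames
  }
  # stance frames are already thresholded and quantized by generate_stance
  rec <- pressure_recording(frames, pitch_mm = cfg$pitch_mm,
                            rate_hz = cfg$rate_hz, id = row$id,
                            threshold = FALSE)
  truth <- purrr::map(1:2, function(k) {
    tr <- st[[k]]$truth
    list(
      side = sides[k],
      onset = onsets[k], offset = onsets[k] + tr$offset,
      peak1 = onsets[k] + tr$peak1, peak2 = onsets[k] + tr$peak2,
      peak3 = onsets[k] + tr$peak3,
      landmarks = tr$landmarks
    )
  })
  names(truth) <- sides
  list(recording = rec, truth = truth)
}
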