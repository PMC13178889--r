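#' Pipeline configuration
#'
#' Orchestration settings for the end-to-end analysis: input source
#' (synthetic cohort config or a manifest CSV of recordings on disk),
#' analysis timings, time-normalization resolution, permutation settings,
#' output directory and master seed.
#'
#' @param synth A [synth_config()] (synthetic input), or `NULL`.
#' @param manifest_path Path to a manifest CSV (file input), or `NULL`.
#'   Exactly one of `synth`/`manifest_path` must be given.
#' @param grid Standard grid for spatial analyses.
#' @param timings Spatial analysis timings, a subset of `"peak1"`,
#'   `"peak2"`, `"peak3"`, `"transient1"`, `"transient2"`.
#' @param average3 Average pressure maps across the three neighbouring
#'   frames around each timing (robustness variant).
#' @param n_points Time-normalization resolution (50 or 100).
#' @param perm A [perm_config()].
#' @param mirror_left Mirror left feet onto right-foot anatomical
#'   coordinates.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Master seed; cohort generation and permutations draw from
#'   named substreams of it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), manifest_path = NULL,
                            grid = standard_grid(),
                            timings = c("peak1", "peak2", "peak3",
                                        "transient1", "transient2"),
                            average3 = FALSE, n_points = 50,
                            perm = perm_config(), mirror_left = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(synth) == is.null(manifest_path)) {
    abort("exactly one input source (synth or manifest_path) must be given")
  }
  if (!n_points %in% c(50, 100)) abort("n_points must be 50 or 100")
  bad <- setdiff(timings, c("peak1", "peak2", "peak3", "transient1", "transient2"))
  if (length(bad) > 0) abort(paste0("unknown timing: ", bad[1]))
  structure(list(synth = synth, manifest_path = manifest_path, grid = grid,
                 timings = timings, average3 = average3, n_points = n_points,
                 perm = perm, mirror_left = mirror_left, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

# Match segmented stances to feet by testing which foot's Landmark 1 falls
# inside (a slightly padded) stance bounding box.
match_stance_side <- function(stances, lms, pad = 3) {
  vapply(stances, function(st) {
    hit <- vapply(c("left", "right"), function(side) {
      L1 <- lms[[side]]$L1
      L1[1] >= st$row0 - pad && L1[1] <= st$row0 + nrow(st$mask) - 1 + pad &&
        L1[2] >= st$col0 - pad && L1[2] <= st$col0 + ncol(st$mask) - 1 + pad
    }, logical(1))
    if (sum(hit) != 1) NA_character_ else c("left", "right")[which(hit)]
  }, character(1))
}

# Full feature extraction for one participant: scalar parameters, per-foot
# standardized weight-normalized maps at the requested timings, and
# per-foot time series.
participant_features <- function(rec, lms, mass, grid, timings, n_points,
                                 mirror_left = TRUE, average3 = FALSE) {
  stances <- segment_stances(rec)
  if (length(stances) < 2) {
    return(list(ok = FALSE, reason = "expected two stances"))
  }
  sides <- match_stance_side(stances, lms)
  if (anyNA(sides) || length(unique(sides)) != 2) {
    return(list(ok = FALSE, reason = "could not assign stances to feet"))
  }
  gait <- basic_gait_params(stances[1:2], list(lms[[sides[1]]], lms[[sides[2]]]),
                            sides, rate_hz = rec$rate_hz, pitch_mm = rec$pitch_mm)
  per_side <- list()
  for (k in seq_along(stances)[1:2]) {
    st <- stances[[k]]; side <- sides[k]
    pp <- pressure_params(st)
    force <- stance_force_series(st)
    pk <- detect_m_peaks(force)
    tp <- NULL; maps <- NULL
    if (pk$valid) {
      tp <- temporal_params(pk, onset = 0, offset = st$offset - st$onset,
                            rate_hz = rec$rate_hz)
      frame_at <- c(peak1 = tp$peak1, peak2 = tp$peak2, peak3 = tp$peak3,
                    transient1 = tp$transient1, transient2 = tp$transient2)
      mirror <- mirror_left && side == "left"
      n_local <- dim(st$frames)[1]
      maps <- lapply(timings, function(tm) {
        f0 <- frame_at[[tm]]
        fs <- if (average3) pmax(pmin(f0 + (-1:1), n_local - 1), 0) else f0
        sf <- standardize_foot(st, lms[[side]], grid = grid, mirror = mirror,
                               frames = fs)
        m <- apply(sf$grid, c(2, 3), mean)
        weight_normalize(m, mass)
      })
      names(maps) <- timings
    }
    series <- time_series_set(st, mass, n_points = n_points)
    per_side[[side]] <- list(pressure = pp, temporal = tp, maps = maps,
                             series = series, m_valid = pk$valid)
  }
  avg2 <- function(get) {
    vals <- purrr::map_dbl(per_side, function(s) {
      v <- get(s); if (is.null(v)) NA_real_ else v
    })
    mean(vals)
  }
  row <- tibble(
    step_length = gait$step_length, step_duration = gait$step_duration,
    cadence = gait$cadence, speed = gait$speed, foot_angle = gait$foot_angle,
    contact_area = avg2(function(s) s$pressure$contact_area),
    peak_pressure = avg2(function(s) s$pressure$peak_pressure),
    max_force = avg2(function(s) s$pressure$max_force),
    interval1 = avg2(function(s) s$temporal$interval1),
    interval2 = avg2(function(s) s$temporal$interval2),
    interval3 = avg2(function(s) s$temporal$interval3),
    interval4 = avg2(function(s) s$temporal$interval4),
    prop_interval1 = avg2(function(s) s$temporal$prop_interval1),
    prop_interval2 = avg2(function(s) s$temporal$prop_interval2),
    prop_interval3 = avg2(function(s) s$temporal$prop_interval3),
    prop_interval4 = avg2(function(s) s$temporal$prop_interval4)
  )
  list(ok = TRUE, row = row, per_side = per_side)
}

#' Extract cohort-level features
#'
#' Streams through the participants of a synthetic cohort (or a manifest of
#' recordings on disk), extracting scalar parameters, standardized
#' weight-normalized pressure maps at the analysis timings, and
#' time-normalized stance series. Memory stays flat: recordings are
#' materialized (or read) one participant at a time and discarded.
#'
#' Stances whose total-force curve fails M-peak detection are excluded from
#' the temporal parameters and the peak-anchored spatial maps, but retained
#' for contact-area and COP series.
#'
#' @param cohort A `synth_cohort`, or a manifest tibble whose `recording`
#'   column holds frame-stack file paths.
#' @param grid Standard grid for the spatial maps.
#' @param timings Timings at which maps are extracted (see
#'   [pipeline_config()]); empty vector skips spatial maps.
#' @param n_points Time-normalization resolution.
#' @param mirror_left,average3 See [pipeline_config()].
#' @return List: `params` (tibble, one row per participant with
#'   demographics and all scalar parameters), `maps`
#'   (`maps[[side]][[timing]]` = subject x pixel matrix), `series`
#'   (`series[[side]][[name]]` = subject x n_points matrix), `map_subjects`
#'   (ids per row of the map matrices), `excluded` (ids of stances failing
#'   M-peak detection).
#' @export
cohort_features <- function(cohort, grid = standard_grid(),
                            timings = c("peak1", "peak2", "peak3",
                                        "transient1", "transient2"),
                            n_points = 50, mirror_left = TRUE,
                            average3 = FALSE) {
  is_synth <- inherits(cohort, "synth_cohort")
  manifest <- if (is_synth) cohort$manifest else cohort
  n <- nrow(manifest)
  series_names <- c("total_force_bw", "avg_pressure", "contact_area",
                    "cop_x", "cop_y")
  rows <- vector("list", n)
  maps <- list(); series <- list(); map_sub <- list()
  excluded <- character(0)
  for (side in c("left", "right")) {
    maps[[side]] <- stats::setNames(vector("list", length(timings)), timings)
    series[[side]] <- stats::setNames(vector("list", length(series_names)),
                                      series_names)
    map_sub[[side]] <- character(0)
  }
  for (i in seq_len(n)) {
    m <- manifest[i, ]
    if (is_synth) {
      rec <- participant_recording(cohort, i)$recording
    } else {
      rec <- read_recording(m$recording)
    }
    lms <- list(
      left = list(L1 = c(m$left_l1_row, m$left_l1_col),
                  L2 = c(m$left_l2_row, m$left_l2_col)),
      right = list(L1 = c(m$right_l1_row, m$right_l1_col),
                   L2 = c(m$right_l2_row, m$right_l2_col))
    )
    ft <- participant_features(rec, lms, mass = m$weight, grid = grid,
                               timings = timings, n_points = n_points,
                               mirror_left = mirror_left, average3 = average3)
    if (!ft$ok) {
      excluded <- c(excluded, paste0(m$id, " (", ft$reason, ")"))
      next
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(id = m$id, sex = m$sex, age = m$age, height = m$height,
             weight = m$weight, bmi = m$bmi),
      ft$row
    )
    for (side in names(ft$per_side)) {
      ps <- ft$per_side[[side]]
      for (nm in series_names) {
        series[[side]][[nm]] <- rbind(series[[side]][[nm]],
                                      ps$series[[nm]])
      }
      if (!is.null(ps$maps)) {
        for (tm in timings) {
          maps[[side]][[tm]] <- rbind(maps[[side]][[tm]],
                                      as.vector(ps$maps[[tm]]))
        }
        map_sub[[side]] <- c(map_sub[[side]], m$id)
      } else {
        excluded <- c(excluded, paste0(m$id, " (", side,
                                       ": no M-shape)"))
      }
    }
  }
  for (side in c("left", "right")) {
    for (tm in names(maps[[side]])) {
      if (!is.null(maps[[side]][[tm]])) {
        attr(maps[[side]][[tm]], "map_dim") <- grid$dim
      }
    }
  }
  list(params = purrr::list_rbind(purrr::compact(rows)), maps = maps,
       series = series, map_subjects = map_sub, excluded = excluded,
       grid = grid)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, extracts features, computes the scalar
#' group-comparison tables, covariate-adjusted sex effects, per-foot
#' spatial cluster tests at the configured timings, and per-foot temporal
#' cluster tests for the three pressure series and the two COP coordinate
#' series. Reruns with an identical configuration and seed give identical
#' numeric outputs. When `config$out_dir` is set, the parameter and cluster
#' tables are written as CSV together with a run log.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pedocluster_result`: list with `params`,
#'   `tables` (anthropometrics, gait, pressure/temporal), `adjusted`
#'   (covariate-adjusted fits), `spatial` (`spatial[[side]][[timing]]` =
#'   [cluster_test()] result), `temporal` (`temporal[[side]][[series]]`),
#'   `features`, `excluded`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  if (!is.null(config$synth)) {
    synth <- config$synth
    synth$seed <- substream_seed(config$seed, "cohort")
    cohort <- generate_cohort(synth)
  } else {
    cohort <- read_manifest(config$manifest_path)
  }
  feats <- cohort_features(cohort, grid = config$grid,
                           timings = config$timings,
                           n_points = config$n_points,
                           mirror_left = config$mirror_left,
                           average3 = config$average3)
  params <- feats$params
  tables <- list(
    anthropometrics = group_comparison_table(
      params, c("age", "height", "weight", "bmi")),
    gait = group_comparison_table(
      params, c("step_length", "step_duration", "cadence", "speed",
                "foot_angle")),
    pressure_temporal = group_comparison_table(
      params, c("interval1", "interval2", "interval3", "interval4",
                "prop_interval1", "prop_interval2", "prop_interval3",
                "prop_interval4", "contact_area", "peak_pressure",
                "max_force"))
  )
  adj_vars <- c("contact_area", "max_force", "peak_pressure",
                "prop_interval1", "prop_interval2", "prop_interval3",
                "prop_interval4")
  complete <- stats::na.omit(params)
  if (nrow(complete) >= 9) {   # need more observations than model terms
    adjusted <- purrr::map(adj_vars,
                           function(v) adjusted_sex_effect(complete, v))
    names(adjusted) <- adj_vars
  } else {
    adjusted <- stats::setNames(vector("list", length(adj_vars)), adj_vars)
  }

  spatial <- list(); temporal <- list()
  pc <- config$perm
  k <- 0
  for (side in c("left", "right")) {
    spatial[[side]] <- list()
    for (tm in config$timings) {
      M <- feats$maps[[side]][[tm]]
      if (is.null(M)) next
      sx <- params$sex[match(feats$map_subjects[[side]], params$id)]
      k <- k + 1
      pck <- pc; pck$seed <- substream_seed(config$seed, paste0("perm", k))
      spatial[[side]][[tm]] <- cluster_test(
        M[sx == "female", , drop = FALSE] |> with_dim(config$grid$dim),
        M[sx == "male", , drop = FALSE] |> with_dim(config$grid$dim),
        pck)
    }
    temporal[[side]] <- list()
    for (nm in names(feats$series[[side]])) {
      S <- feats$series[[side]][[nm]]
      if (is.null(S)) next
      sx <- params$sex
      k <- k + 1
      pck <- pc; pck$seed <- substream_seed(config$seed, paste0("perm", k))
      # coverage rule is meant for contact maps; time series are dense
      pck$min_group_coverage <- 0
      temporal[[side]][[nm]] <- cluster_test(
        S[sx == "female", , drop = FALSE],
        S[sx == "male", , drop = FALSE], pck)
    }
  }
  res <- structure(list(params = params, tables = tables,
                        adjusted = adjusted, spatial = spatial,
                        temporal = temporal, features = feats,
                        excluded = feats$excluded, config = config),
                   class = "pedocluster_result")
  if (!is.null(config$out_dir)) write_result(res, config$out_dir)
  res
}

with_dim <- function(m, d) { attr(m, "map_dim") <- d; m }

# Serialize the result bundle: parameter table, comparison tables, cluster
# tables, and a run log.
write_result <- function(res, out_dir) {
  readr::write_csv(res$params, file.path(out_dir, "participant_parameters.csv"))
  for (nm in names(res$tables)) {
    readr::write_csv(res$tables[[nm]], file.path(out_dir, paste0("table_", nm, ".csv")))
  }
  cl <- list()
  for (side in names(res$spatial)) {
    for (tm in names(res$spatial[[side]])) {
      t <- tidy(res$spatial[[side]][[tm]])
      if (nrow(t) > 0) cl[[length(cl) + 1]] <- mutate(t, side = side, at = tm,
                                                      domain = "spatial")
    }
  }
  for (side in names(res$temporal)) {
    for (nm in names(res$temporal[[side]])) {
      t <- tidy(res$temporal[[side]][[nm]])
      if (nrow(t) > 0) cl[[length(cl) + 1]] <- mutate(t, side = side, at = nm,
                                                      domain = "temporal")
    }
  }
  clusters <- if (length(cl) > 0) purrr::list_rbind(cl) else
    tibble(cluster_id = integer(), side = character())
  readr::write_csv(clusters, file.path(out_dir, "cluster_results.csv"))
  log <- c(
    sprintf("pedocluster %s", as.character(utils::packageVersion("pedocluster"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %s", res$config$seed),
    sprintf("n_perm: %d", res$config$perm$n_perm),
    sprintf("n_points: %d", res$config$n_points),
    sprintf("participants: %d", nrow(res$params)),
    sprintf("excluded: %s",
            if (length(res$excluded) == 0) "none" else
              paste(res$excluded, collapse = "; "))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pedocluster_result <- function(x, ...) {
  cat(sprintf("<pedocluster_result> %d participants (%d female, %d male)\n",
              nrow(x$params), sum(x$params$sex == "female"),
              sum(x$params$sex == "male")))
  n_sig <- function(l) sum(purrr::map_int(l, function(t) sum(t$clusters$significant)))
  for (side in names(x$spatial)) {
    cat(sprintf("  %s foot: %d significant spatial cluster(s), %d temporal\n",
                side, n_sig(x$spatial[[side]]), n_sig(x$temporal[[side]])))
  }
  invisible(x)
}

#' Human-readable report of a pipeline run
#'
#' Produces a text summary plus, for each analyzed timing and series, the
#' figure objects: group-mean maps normalized to [0, 1] over both sexes,
#' difference maps with significant clusters outlined, and group-mean
#' series with significant temporal windows shaded.
#'
#' @param res A `pedocluster_result`.
#' @param out_dir Directory for figure files (PNG) and the summary;
#'   `NULL` returns the objects without writing.
#' @return List with `summary` (character vector) and `figures` (named
#'   list of ggplot objects), invisibly printed.
#' @export
make_report <- function(res, out_dir = NULL) {
  lines <- c("Plantar pressure sex-difference analysis", "")
  figures <- list()
  any_sig <- FALSE
  for (side in names(res$spatial)) {
    for (tm in names(res$spatial[[side]])) {
      ct <- res$spatial[[side]][[tm]]
      ns <- sum(ct$clusters$significant)
      any_sig <- any_sig || ns > 0
      lines <- c(lines, sprintf("%s foot, %s: %d significant spatial cluster(s)",
                                side, tm, ns))
      figures[[paste0("spatial_", side, "_", tm)]] <- autoplot(ct)
    }
  }
  for (side in names(res$temporal)) {
    for (nm in names(res$temporal[[side]])) {
      ct <- res$temporal[[side]][[nm]]
      ns <- sum(ct$clusters$significant)
      any_sig <- any_sig || ns > 0
      lines <- c(lines, sprintf("%s foot, %s series: %d significant temporal window(s)",
                                side, nm, ns))
      figures[[paste0("temporal_", side, "_", nm)]] <- autoplot(ct)
    }
  }
  if (!any_sig) lines <- c(lines, "", "No significant clusters were detected.")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "report.txt"))
    for (nm in names(figures)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), figures[[nm]],
                      width = 7, height = 4, dpi = 120)
    }
  }
  invisible(list(summary = lines, figures = figures))
}
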