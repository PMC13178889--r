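#' @export
tidy.cluster_perm_test <- function(x, ...) {
  out <- x$clusters
  attr(out, "members") <- NULL
  out
}

#' @export
glance.cluster_perm_test <- function(x, ...) {
  tibble(
    n_testable = sum(x$stat_map$mask),
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    n_relabelings = length(x$null),
    method = x$method,
    cluster_alpha = x$config$cluster_alpha,
    cluster_forming_p = x$config$cluster_forming_p,
    cluster_stat = x$config$cluster_stat
  )
}

#' @export
tidy.stat_map <- function(x, ...) {
  if (length(x$dim) == 2) {
    tibble(
      row = rep(seq_len(x$dim[1]), times = x$dim[2]),
      col = rep(seq_len(x$dim[2]), each = x$dim[1]),
      t = x$t, p = x$p, df = x$df, testable = x$mask
    )
  } else {
    tibble(point = seq_along(x$t), t = x$t, p = x$p, df = x$df,
           testable = x$mask)
  }
}

#' @export
tidy.sex_adjusted_fit <- function(x, ...) {
  dplyr::left_join(
    x$coefficients,
    tibble(term = names(x$vif), vif = unname(x$vif)),
    by = "term"
  )
}

#' @export
glance.sex_adjusted_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, df_residual = x$fit$df.residual,
         max_vif = max(x$vif))
}

#' Plot a cluster-based permutation test
#'
#' 2D tests are drawn as a t-statistic map with the member pixels of
#' significant clusters outlined; 1D tests as the t series with significant
#' temporal windows shaded.
#'
#' @param object A `cluster_perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_perm_test <- function(object, ...) {
  sm <- object$stat_map
  sig <- cluster_mask(object, significant_only = TRUE)
  if (length(sm$dim) == 2) {
    df <- tidy(sm)
    df$significant <- as.vector(sig)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
      ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                         fill = NA, colour = "red", linewidth = 0.3) +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "firebrick", na.value = "grey92") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "mediolateral (cells)", y = "progression (cells)",
                    fill = "t") +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(sm)
    runs <- label_components(sig)
    bands <- if (max(runs) > 0) {
      purrr::map(seq_len(max(runs)), function(k) {
        idx <- which(runs == k)
        tibble(xmin = min(idx), xmax = max(idx))
      }) |> purrr::list_rbind()
    } else tibble(xmin = numeric(), xmax = numeric())
    ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$t)) +
      ggplot2::geom_rect(data = bands,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, fill = "palegreen",
                         alpha = 0.5) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::labs(x = "normalized time point", y = "t statistic") +
      ggplot2::theme_minimal()
  }
}

#' Group-mean pressure maps and difference map
#'
#' Renders the two group-mean maps, jointly normalized to [0, 1] by the
#' minimum and maximum observed across both groups, next to the
#' group-difference map (group A minus group B), optionally outlining a
#' set of pixels (e.g. significant cluster members).
#'
#' @param group_a,group_b Subject stacks on a common grid (see
#'   [pointwise_tmap()]).
#' @param outline Optional logical matrix of pixels to outline on the
#'   difference panel.
#' @param labels Panel labels for the two groups.
#' @param dim Grid dimension `c(rows, cols)`; needed when the inputs are
#'   plain matrices without a `map_dim` attribute.
#' @return A ggplot object (facetted).
#' @export
plot_mean_pressure_maps <- function(group_a, group_b, outline = NULL,
                                    labels = c("female", "male"),
                                    dim = NULL) {
  a <- as_subject_matrix(group_a); b <- as_subject_matrix(group_b)
  if (!is.null(dim)) a$dim <- b$dim <- dim
  if (length(a$dim) != 2) {
    abort("2D maps required; supply `dim = c(rows, cols)` for plain matrices")
  }
  ma <- colMeans(a$mat); mb <- colMeans(b$mat)
  rng <- range(c(ma, mb))
  norm <- function(v) (v - rng[1]) / diff(rng)
  d <- a$dim
  mk <- function(v, panel) {
    tibble(row = rep(seq_len(d[1]), times = d[2]),
           col = rep(seq_len(d[2]), each = d[1]),
           value = v, panel = panel)
  }
  df <- bind_rows(mk(norm(ma), labels[1]), mk(norm(mb), labels[2]))
  diff_df <- mk(ma - mb, "difference")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "pressure\n[0-1]") +
    ggplot2::theme_minimal()
  if (!is.null(outline)) {
    odf <- mk(as.numeric(outline), "difference")
    odf <- dplyr::filter(odf, .data$value > 0)
    if (nrow(odf) > 0) {
      p <- p + ggplot2::geom_tile(data = odf, fill = NA, colour = "red",
                                  linewidth = 0.3)
    }
  }
  p
}

#' Plot group-mean stance series with significant windows
#'
#' @param series_a,series_b Subject x time-point matrices.
#' @param test Optional 1D `cluster_perm_test` whose significant windows
#'   are shaded.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_series_comparison <- function(series_a, series_b, test = NULL,
                                   ylab = "value") {
  n_pt <- ncol(series_a)
  mk <- function(m, g) {
    tibble(time = seq_len(n_pt), mean = colMeans(m),
           se = apply(m, 2, sd) / sqrt(nrow(m)), group = g)
  }
  df <- bind_rows(mk(series_a, "female"), mk(series_b, "male"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                        colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(female = "red", male = "blue")) +
    ggplot2::scale_fill_manual(values = c(female = "red", male = "blue")) +
    ggplot2::labs(x = "normalized time point", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(test)) {
    sig <- cluster_mask(test, significant_only = TRUE)
    runs <- label_components(sig)
    if (max(runs) > 0) {
      bands <- purrr::map(seq_len(max(runs)), function(k) {
        idx <- which(runs == k)
        tibble(xmin = min(idx), xmax = max(idx))
      }) |> purrr::list_rbind()
      p <- p + ggplot2::geom_rect(data = bands,
                                  ggplot2::aes(xmin = .data$xmin,
                                               xmax = .data$xmax,
                                               ymin = -Inf, ymax = Inf),
                                  inherit.aes = FALSE, fill = "palegreen",
                                  alpha = 0.4)
    }
  }
  p
}
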