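#' Standard foot grid
#'
#' The standardized foot coordinate system places Landmark 1 (most posterior
#' heel point) at progression coordinate `y = 10` A.U. on the foot midline
#' (`x = 0`) and Landmark 2 (tip of the second toe) at `y = 110`, so the
#' landmark distance is 100 A.U. The grid spans `y` in `[0, 120)`
#' (progression) and `x` in `[-30, 30)` (mediolateral, medial negative for a
#' right foot; left feet are mirrored before pooling). The default
#' resolution is 120 x 60 cells of 1 A.U.; coarser grids cover the same
#' extent with proportionally larger cells.
#'
#' @param n_row,n_col Grid resolution (progression x mediolateral).
#' @return A list with `y`, `x` (cell-center coordinates in A.U.), `sy`,
#'   `sx` (cell sizes), and `dim`.
#' @export
#' @examples
#' g <- standard_grid(40, 20)
#' g$sy  # 3 A.U. per cell
standard_grid <- function(n_row = 120, n_col = 60) {
  sy <- 120 / n_row
  sx <- 60 / n_col
  list(
    y = (seq_len(n_row) - 1) * sy,
    x = -30 + sx / 2 + (seq_len(n_col) - 1) * sx,
    sy = sy, sx = sx, dim = c(n_row, n_col)
  )
}

# Gaussian lobe parameters of the synthetic footprint, in standard A.U.
# coordinates of a RIGHT foot (medial x < 0). Amplitudes are relative; each
# zone is normalized to unit integral before use so they only shape the
# within-zone distribution.
foot_lobes <- function() {
  tibble(
    lobe = c("heel", "midfoot", "mt1", "mt2", "mt3", "mt4", "mt5",
             "hallux", "toe2", "lateral_toes"),
    zone = c("heel", "midfoot", rep("forefoot", 8)),
    cy = c(25, 48, 72, 76, 76, 74, 71, 95, 103, 94),
    cx = c(0, 8, -10, -3, 4, 10, 15, -8, -1, 8),
    sy = c(8, 10, 6, 6, 6, 6, 5, 6, 5, 4),
    sx = c(6, 5, 4.5, 4, 4, 4, 4, 4.5, 3, 4.5),
    amp = c(1.0, 0.22, 0.85, 1.0, 0.7, 0.5, 0.35, 0.7, 0.32, 0.18)
  )
}

# Evaluate the summed lobes of one zone at arbitrary (y, x) coordinates.
# `mirror` flips the mediolateral axis (left feet).
eval_zone <- function(y, x, zone, mirror = FALSE) {
  lb <- foot_lobes()
  lb <- lb[lb$zone == zone, , drop = FALSE]
  if (mirror) lb$cx <- -lb$cx
  out <- 0
  for (i in seq_len(nrow(lb))) {
    out <- out + lb$amp[i] *
      exp(-0.5 * (((y - lb$cy[i]) / lb$sy[i])^2 + ((x - lb$cx[i]) / lb$sx[i])^2))
  }
  out
}

#' Synthetic footprint pressure template on the standard grid
#'
#' Evaluates the smooth multi-lobe footprint model (heel, lateral midfoot,
#' five metatarsal heads, toes) on a standard grid. Values below
#' `support_frac` of the template maximum are set to 0, giving the template
#' a realistic compact contact area.
#'
#' @param grid A grid from [standard_grid()].
#' @param mirror Mirror the mediolateral axis (left-foot anatomy).
#' @param support_frac Relative cutoff defining the contact support.
#' @return Numeric matrix `n_row x n_col` (arbitrary relative units,
#'   max = 1).
#' @export
foot_template <- function(grid = standard_grid(), mirror = FALSE,
                          support_frac = 0.02) {
  Y <- matrix(grid$y, grid$dim[1], grid$dim[2])
  X <- matrix(grid$x, grid$dim[1], grid$dim[2], byrow = TRUE)
  tpl <- eval_zone(Y, X, "heel", mirror) +
    eval_zone(Y, X, "midfoot", mirror) +
    eval_zone(Y, X, "forefoot", mirror)
  tpl <- tpl / max(tpl)
  tpl[tpl < support_frac] <- 0
  tpl
}

# Elliptical anatomical region definitions on the standard coordinate
# system (right-foot A.U.): calcaneus under the heel, second-metatarsal head
# region under the forefoot. The two presets are disjoint by construction.
region_params <- function() {
  list(
    calcaneus = list(cy = 25, cx = 0, ry = 10, rx = 8),
    second_metatarsal = list(cy = 76, cx = -3, ry = 7, rx = 5)
  )
}

#' Anatomical region preset masks
#'
#' Pixel masks of the calcaneal and second-metatarsal regions on a standard
#' grid, used to inject and recover localized group effects.
#'
#' @param name `"calcaneus"` or `"second_metatarsal"`.
#' @param grid A grid from [standard_grid()].
#' @param mirror Mirror the mediolateral axis (left-foot anatomy).
#' @return Logical matrix on the grid.
#' @export
#' @examples
#' sum(region_preset("calcaneus", standard_grid(40, 20)))
region_preset <- function(name = c("calcaneus", "second_metatarsal"),
                          grid = standard_grid(), mirror = FALSE) {
  name <- match.arg(name)
  p <- region_params()[[name]]
  cx <- if (mirror) -p$cx else p$cx
  Y <- matrix(grid$y, grid$dim[1], grid$dim[2])
  X <- matrix(grid$x, grid$dim[1], grid$dim[2], byrow = TRUE)
  ((Y - p$cy) / p$ry)^2 + ((X - cx) / p$rx)^2 <= 1
}
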