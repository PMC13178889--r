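#' Permutation-test configuration
#'
#' Defaults follow standard practice for cluster-based permutation mapping:
#' a pointwise cluster-forming threshold of p = .01, a cluster-level
#' significance threshold of p = .05, 1000 Monte Carlo label permutations,
#' 8-connectivity for 2D maps (index adjacency for 1D series), and a
#' coverage rule requiring a point to be non-zero in at least 50% of the
#' subjects of each group to enter testing.
#'
#' @param cluster_forming_p Pointwise two-sided p threshold forming
#'   clusters.
#' @param cluster_alpha Cluster-level (family-wise) significance threshold.
#' @param n_perm Number of Monte Carlo permutations.
#' @param connectivity 8 (diagonal neighbours contiguous) or 4, for 2D maps.
#' @param seed Integer seed for the permutation stream (`NULL` = current
#'   RNG state).
#' @param min_group_coverage Minimum fraction of subjects per group with a
#'   non-zero value for a point to be testable.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param cluster_stat Cluster-level statistic: `"mass"` (sum of |t| over
#'   members) or `"max_t"` (largest |t| in the cluster).
#' @param method `"monte_carlo"`, `"exhaustive"` (enumerate all distinct
#'   relabelings), or `"auto"` (exhaustive whenever the number of distinct
#'   relabelings does not exceed `n_perm`).
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(cluster_forming_p = 0.01, cluster_alpha = 0.05,
                        n_perm = 1000, connectivity = 8, seed = NULL,
                        min_group_coverage = 0.5, var_equal = FALSE,
                        cluster_stat = c("mass", "max_t"),
                        method = c("auto", "monte_carlo", "exhaustive")) {
  if (!(cluster_forming_p > 0 && cluster_forming_p < cluster_alpha)) {
    abort("need 0 < cluster_forming_p < cluster_alpha")
  }
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  structure(list(
    cluster_forming_p = cluster_forming_p, cluster_alpha = cluster_alpha,
    n_perm = as.integer(n_perm), connectivity = connectivity, seed = seed,
    min_group_coverage = min_group_coverage, var_equal = var_equal,
    cluster_stat = match.arg(cluster_stat), method = match.arg(method)
  ), class = "perm_config")
}

# Coerce a group of maps/series to a subject x point matrix plus the
# spatial dimension. Accepts: subject x point matrix (dim attr optional),
# subject x H x W array, list of matrices/vectors.
as_subject_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    dims <- dim(x[[1]])
    mat <- do.call(rbind, lapply(x, as.vector))
    return(list(mat = mat, dim = if (is.null(dims)) length(x[[1]]) else dims))
  }
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    return(list(mat = matrix(x, d[1], d[2] * d[3]), dim = d[2:3]))
  }
  if (is.matrix(x)) {
    d <- attr(x, "map_dim")
    return(list(mat = x, dim = if (is.null(d)) ncol(x) else d))
  }
  abort("cannot interpret group data: use a subject x point matrix, a subject x H x W array, or a list of maps")
}

# Vectorized two-sample t statistics on the columns of Xa/Xb (or on pooled
# sums). Returns t, df, p and a zero-variance counter. Welch by default.
welch_cols <- function(sA, sA2, nA, sB, sB2, nB, var_equal = FALSE) {
  mA <- sA / nA; mB <- sB / nB
  vA <- pmax((sA2 - nA * mA^2) / (nA - 1), 0)
  vB <- pmax((sB2 - nB * mB^2) / (nB - 1), 0)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- rep(nA + nB - 2, length(sA))
  } else {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  zero <- se2 <= 0 | !is.finite(df)
  t <- (mA - mB) / sqrt(se2)
  t[zero] <- 0
  df[zero] <- nA + nB - 2
  p <- 2 * pt(-abs(t), df)
  p[zero] <- 1
  list(t = t, df = df, p = p, n_zero_var = sum(zero))
}

#' Pointwise two-sample t-map
#'
#' Computes a two-sample t statistic (Welch by default) at every testable
#' point of a 2D pressure map or 1D time series, pixel by pixel. A point is
#' testable when it is non-zero in at least `min_group_coverage` of the
#' subjects of *each* group; other points are masked. Points with zero
#' variance in both groups get t = 0 (counted in `n_zero_var`).
#'
#' @param group_a,group_b Subject stacks: subject x H x W arrays, subject x
#'   point matrices, or lists of maps/series. Group A minus group B defines
#'   the sign.
#' @param config A [perm_config()].
#' @return Object of class `stat_map`: list with `t`, `p`, `df` (vectors
#'   over points; `NA` off-mask), `mask`, `dim`, `n_a`, `n_b`,
#'   `n_zero_var`.
#' @export
pointwise_tmap <- function(group_a, group_b, config = perm_config()) {
  a <- as_subject_matrix(group_a); b <- as_subject_matrix(group_b)
  if (!identical(a$dim, b$dim)) abort("groups must share a common grid")
  if (nrow(a$mat) < 2 || nrow(b$mat) < 2) abort("need >= 2 subjects per group")
  mask <- colMeans(a$mat != 0) >= config$min_group_coverage &
    colMeans(b$mat != 0) >= config$min_group_coverage
  t <- p <- df <- rep(NA_real_, ncol(a$mat))
  nz <- 0L
  if (any(mask)) {
    Xa <- a$mat[, mask, drop = FALSE]; Xb <- b$mat[, mask, drop = FALSE]
    w <- welch_cols(colSums(Xa), colSums(Xa^2), nrow(Xa),
                    colSums(Xb), colSums(Xb^2), nrow(Xb),
                    var_equal = config$var_equal)
    t[mask] <- w$t; p[mask] <- w$p; df[mask] <- w$df
    nz <- w$n_zero_var
    if (nz > 0) warn(sprintf("%d testable point(s) had zero variance in both groups; t set to 0", nz))
  }
  structure(list(t = t, p = p, df = df, mask = mask, dim = a$dim,
                 n_a = nrow(a$mat), n_b = nrow(b$mat), n_zero_var = nz),
            class = "stat_map")
}

# Cluster the given flat point indices (into a grid of dimension `dims`)
# into contiguous components. Returns a list of integer index vectors.
cluster_points <- function(idx, dims, connectivity = 8) {
  k <- length(idx)
  if (k == 0) return(list())
  if (k == 1) return(list(idx))
  if (length(dims) == 2) {
    r <- ((idx - 1) %% dims[1]) + 1
    c <- ((idx - 1) %/% dims[1]) + 1
    dr <- abs(outer(r, r, `-`)); dc <- abs(outer(c, c, `-`))
    adj <- if (connectivity == 8) dr <= 1 & dc <= 1 else dr + dc <= 1
  } else {
    adj <- abs(outer(idx, idx, `-`)) <= 1
  }
  comp <- integer(k); cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nb <- which(matrixStats_any(adj, frontier) & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  lapply(seq_len(cur), function(g) idx[comp == g])
}

# any() over the rows of adj restricted to `cols`, vectorized
matrixStats_any <- function(adj, cols) {
  if (length(cols) == 1) adj[, cols] else rowSums(adj[, cols, drop = FALSE]) > 0
}

#' Form contiguity clusters from a t-map
#'
#' Points with pointwise p below the cluster-forming threshold are split by
#' the sign of t and joined into contiguous clusters (8-connectivity for 2D
#' maps, index adjacency for 1D series). The cluster-level statistic is the
#' cluster mass, the sum of |t| over members (or the maximum |t| when
#' configured).
#'
#' @param stat A `stat_map` from [pointwise_tmap()].
#' @param config A [perm_config()].
#' @return A tibble with one row per cluster (`cluster_id`, `sign`, `size`,
#'   `mass`, `max_t`) ordered by decreasing mass, with the member point
#'   indices (column-major) in the `members` attribute (a list). No
#'   super-threshold points yields a zero-row tibble.
#' @export
form_clusters <- function(stat, config = perm_config()) {
  super <- which(!is.na(stat$p) & stat$p < config$cluster_forming_p & stat$t != 0)
  rows <- list(); members <- list()
  for (sgn in c(1, -1)) {
    idx <- super[sign(stat$t[super]) == sgn]
    for (cl in cluster_points(idx, stat$dim, config$connectivity)) {
      rows[[length(rows) + 1]] <- tibble(
        sign = if (sgn > 0) "positive" else "negative",
        size = length(cl),
        mass = sum(abs(stat$t[cl])),
        max_t = max(abs(stat$t[cl]))
      )
      members[[length(members) + 1]] <- cl
    }
  }
  if (length(rows) == 0) {
    out <- tibble(cluster_id = integer(), sign = character(),
                  size = integer(), mass = numeric(), max_t = numeric())
    attr(out, "members") <- list()
    return(out)
  }
  out <- bind_rows(rows)
  ord <- order(-out$mass)
  out <- out[ord, ]
  out$cluster_id <- seq_len(nrow(out))
  out <- out[, c("cluster_id", "sign", "size", "mass", "max_t")]
  attr(out, "members") <- members[ord]
  out
}

# Cluster statistic used for both observed clusters and the null.
cluster_stat_value <- function(clusters, config) {
  if (config$cluster_stat == "max_t") clusters$max_t else clusters$mass
}

# Max cluster statistic of one (relabeled) dataset, over both signs.
# Works on the masked matrix only; returns 0 when nothing is
# super-threshold.
max_cluster_stat <- function(Xm, X2m, totS, totS2, zA, nA, nB, dims_masked,
                             mask_idx, dims, config) {
  sA <- crossprod(Xm, zA)[, 1]
  sA2 <- crossprod(X2m, zA)[, 1]
  w <- welch_cols(sA, sA2, nA, totS - sA, totS2 - sA2, nB,
                  var_equal = config$var_equal)
  super_local <- which(w$p < config$cluster_forming_p & w$t != 0)
  if (length(super_local) == 0) return(0)
  best <- 0
  for (sgn in c(1, -1)) {
    loc <- super_local[sign(w$t[super_local]) == sgn]
    if (length(loc) == 0) next
    for (cl in cluster_points(mask_idx[loc], dims, config$connectivity)) {
      tt <- abs(w$t[match(cl, mask_idx)])
      v <- if (config$cluster_stat == "max_t") max(tt) else sum(tt)
      if (v > best) best <- v
    }
  }
  best
}

#' Null distribution of the maximum cluster statistic
#'
#' Generates the max-statistic permutation null: group labels are permuted
#' (group sizes preserved), the t-map and its clusters are recomputed, and
#' the maximum cluster statistic over both signs is recorded (0 when no
#' cluster forms). The testable-point mask is the one defined by the
#' observed grouping and is held fixed across permutations. Monte Carlo
#' permutations are drawn with replacement from the relabeling space; when
#' the number of distinct relabelings does not exceed `n_perm` a warning is
#' emitted (or, under `method = "auto"`/`"exhaustive"`, all distinct
#' relabelings are enumerated instead).
#'
#' @param x Pooled subject stack (all subjects of both groups).
#' @param labels Two-level vector (first level = group A) of length
#'   `nrow(x)`.
#' @param config A [perm_config()]; `config$seed` makes the draw
#'   deterministic.
#' @return Numeric vector of max cluster statistics with attribute
#'   `method` (`"monte_carlo"` or `"exhaustive"`).
#' @export
permutation_null <- function(x, labels, config = perm_config()) {
  pooled <- as_subject_matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != nrow(pooled$mat)) abort("labels must match the pooled stack")
  lev <- levels(labels)
  if (length(lev) != 2) abort("labels must have exactly two levels")
  isA <- labels == lev[1]
  nA <- sum(isA); nB <- sum(!isA)
  mask <- colMeans(pooled$mat[isA, , drop = FALSE] != 0) >= config$min_group_coverage &
    colMeans(pooled$mat[!isA, , drop = FALSE] != 0) >= config$min_group_coverage
  mask_idx <- which(mask)
  n_distinct <- choose(nA + nB, nA)
  method <- config$method
  if (method == "auto") {
    method <- if (n_distinct <= config$n_perm) "exhaustive" else "monte_carlo"
  }
  if (length(mask_idx) == 0) {
    out <- rep(0, if (method == "exhaustive") n_distinct else config$n_perm)
    attr(out, "method") <- method
    return(out)
  }
  Xm <- pooled$mat[, mask_idx, drop = FALSE]
  X2m <- Xm^2
  totS <- colSums(Xm); totS2 <- colSums(X2m)
  n <- nA + nB
  run_one <- function(idxA) {
    zA <- numeric(n); zA[idxA] <- 1
    max_cluster_stat(Xm, X2m, totS, totS2, zA, nA, nB, NULL,
                     mask_idx, pooled$dim, config)
  }
  if (method == "exhaustive") {
    combos <- combn(n, nA)
    null <- apply(combos, 2, run_one)
  } else {
    if (n_distinct <= config$n_perm) {
      warn(sprintf(
        "only %d distinct relabelings exist (< n_perm = %d); sampling with replacement",
        n_distinct, config$n_perm))
    }
    null <- with_seed(config$seed, {
      vapply(seq_len(config$n_perm), function(i) run_one(sample(n, nA)),
             numeric(1))
    })
  }
  attr(null, "method") <- method
  null
}

#' Cluster-based permutation test between two groups
#'
#' Full inference: pointwise t-map, contiguity clusters of super-threshold
#' points, max-statistic permutation null, and permutation-corrected
#' cluster p-values. For Monte Carlo nulls
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, which never falls below
#' `1/(n_perm + 1)`; for exhaustive nulls the exact proportion over all
#' relabelings is used. A cluster is significant when its corrected p-value
#' is at or below `cluster_alpha`. The identical machinery applies to 2D
#' standardized pressure maps and to 1D stance time series (including COP
#' coordinate series).
#'
#' @param group_a,group_b Subject stacks (see [pointwise_tmap()]).
#' @param config A [perm_config()].
#' @return Object of class `cluster_perm_test`: list with `stat_map`,
#'   `clusters` (tibble with `p_corrected`, `significant`, members in the
#'   attribute), `null` (max-statistic null), `config`, `method`.
#' @export
cluster_test <- function(group_a, group_b, config = perm_config()) {
  a <- as_subject_matrix(group_a); b <- as_subject_matrix(group_b)
  attr(a$mat, "map_dim") <- a$dim
  attr(b$mat, "map_dim") <- b$dim
  stat <- pointwise_tmap(a$mat, b$mat, config)
  clusters <- form_clusters(stat, config)
  pooled <- rbind(a$mat, b$mat)
  attr(pooled, "map_dim") <- a$dim
  labels <- rep(c("A", "B"), c(nrow(a$mat), nrow(b$mat)))
  null <- suppressWarnings(permutation_null(pooled, labels, config))
  method <- attr(null, "method")
  obs <- cluster_stat_value(clusters, config)
  if (nrow(clusters) > 0) {
    if (method == "exhaustive") {
      clusters$p_corrected <- vapply(obs, function(v) mean(null >= v), numeric(1))
    } else {
      clusters$p_corrected <- vapply(obs, function(v) {
        (1 + sum(null >= v)) / (1 + length(null))
      }, numeric(1))
    }
    clusters$significant <- clusters$p_corrected <= config$cluster_alpha
  } else {
    clusters$p_corrected <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(stat_map = stat, clusters = clusters, null = null,
                 config = config, method = method),
            class = "cluster_perm_test")
}

#' @export
print.cluster_perm_test <- function(x, ...) {
  cat(sprintf("<cluster_perm_test> %s null, %d relabelings, %s statistic\n",
              x$method, length(x$null), x$config$cluster_stat))
  cat(sprintf("  %d testable points, %d cluster(s), %d significant at alpha = %g\n",
              sum(x$stat_map$mask), nrow(x$clusters),
              sum(x$clusters$significant), x$config$cluster_alpha))
  if (nrow(x$clusters) > 0) print(x$clusters, n = 5)
  invisible(x)
}

#' Significant-cluster membership mask
#'
#' @param test A `cluster_perm_test`.
#' @param significant_only Restrict to significant clusters.
#' @return Logical matrix (2D) or vector (1D) marking member points.
#' @export
cluster_mask <- function(test, significant_only = TRUE) {
  dims <- test$stat_map$dim
  out <- if (length(dims) == 2) matrix(FALSE, dims[1], dims[2]) else
    rep(FALSE, dims)
  members <- attr(test$clusters, "members")
  keep <- if (significant_only) which(test$clusters$significant) else
    seq_len(nrow(test$clusters))
  for (i in keep) out[members[[i]]] <- TRUE
  out
}
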