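# Connected-component labeling on a logical matrix under 8- (default) or
# 4-connectivity, or on a logical vector under index adjacency. Classic
# two-pass run-based labeling: maximal horizontal runs within each column
# strip are provisional nodes, runs in adjacent columns that touch (or
# touch diagonally under 8-connectivity) are unioned, and labels are
# renumbered 1..k in order of first (column-major) occurrence. Returns an
# integer matrix/vector with 0 for inactive cells.
label_components <- function(mask, connectivity = 8) {
  if (is.null(dim(mask)) || length(dim(mask)) < 2L ||
      (is.matrix(mask) && ncol(mask) == 1L)) {
    v <- as.logical(as.vector(mask))
    lab <- integer(length(v))
    if (!any(v)) return(lab)
    runs <- rle(v)
    ids <- cumsum(runs$values)
    return(as.integer(inverse.rle(list(lengths = runs$lengths,
                                       values = ifelse(runs$values, ids, 0L)))))
  }
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  # vertical runs per column (rows are contiguous within a column)
  run_col <- integer(0); run_lo <- integer(0); run_hi <- integer(0)
  for (j in seq_len(W)) {
    col <- mask[, j]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    act <- which(r$values)
    run_col <- c(run_col, rep.int(j, length(act)))
    run_lo <- c(run_lo, starts[act])
    run_hi <- c(run_hi, ends[act])
  }
  n_run <- length(run_col)
  parent <- seq_len(n_run)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  prev_idx <- integer(0); prev_col <- -1L
  for (j in sort(unique(run_col))) {
    cur_idx <- which(run_col == j)
    if (prev_col == j - 1L) {
      for (i in cur_idx) {
        for (k in prev_idx) {
          if (run_lo[i] <= run_hi[k] + slack && run_hi[i] >= run_lo[k] - slack) {
            ri <- find(i); rk <- find(k)
            if (ri != rk) parent[ri] <- rk
          }
        }
      }
    }
    prev_idx <- cur_idx; prev_col <- j
  }
  roots <- vapply(seq_len(n_run), find, integer(1))
  out <- matrix(0L, H, W)
  # order runs column-major so labels appear in first-occurrence order
  ord <- order(run_col, run_lo)
  lab_of_root <- integer(n_run)
  next_lab <- 0L
  for (i in ord) {
    r <- roots[i]
    if (lab_of_root[r] == 0L) {
      next_lab <- next_lab + 1L
      lab_of_root[r] <- next_lab
    }
    out[run_lo[i]:run_hi[i], run_col[i]] <- lab_of_root[r]
  }
  out
}
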