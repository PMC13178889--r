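# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# Naive flood-fill connected-component labeling (explicit stack).
bfs_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  k <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      k <- k + 1L
      stack <- list(c(i, j))
      lab[i, j] <- k
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (q in seq_len(nrow(nb))) {
          r <- p[1] + nb$dr[q]; c <- p[2] + nb$dc[q]
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- k
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Partition of active cells implied by a label map, as a canonical sorted
# list of sorted index vectors (renumbering-invariant comparison).
label_partition <- function(lab) {
  ks <- setdiff(unique(as.vector(lab)), 0L)
  parts <- lapply(ks, function(k) sort(which(lab == k)))
  parts[order(vapply(parts, min, numeric(1)))]
}

# Brute-force max-cluster-mass permutation null for a 1D series,
# enumerating every distinct relabeling. Uses t.test() per point and
# flood-fill clustering on the threshold vector.
exhaustive_null_oracle <- function(x, n_a, forming_p = 0.01) {
  n <- nrow(x)
  combos <- utils::combn(n, n_a)
  apply(combos, 2, function(idxA) {
    t_vec <- p_vec <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
      ht <- stats::t.test(x[idxA, j], x[-idxA, j])
      t_vec[j] <- unname(ht$statistic)
      p_vec[j] <- ht$p.value
    }
    best <- 0
    for (sgn in c(1, -1)) {
      sel <- p_vec < forming_p & sign(t_vec) == sgn
      if (!any(sel)) next
      r <- rle(sel)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        m <- sum(abs(t_vec[starts[k]:ends[k]]))
        if (m > best) best <- m
      }
    }
    best
  })
}

# A minimal synthetic recording: one or two rectangular pressure blocks.
block_recording <- function(blocks, T = 20, H = 12, W = 10, pitch = 5,
                            rate = 100, id = "blk") {
  fr <- array(0, c(T, H, W))
  for (b in blocks) {
    fr[b$t, b$rows, b$cols] <- b$value
  }
  pressure_recording(fr, pitch_mm = pitch, rate_hz = rate, id = id)
}

# Construct a sample with exactly the requested mean and sd.
sample_with_summary <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

tiny_synth_config <- function(n_female = 4, n_male = 3, seed = 101, ...) {
  synth_config(n_female = n_female, n_male = n_male, seed = seed, ...)
}
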