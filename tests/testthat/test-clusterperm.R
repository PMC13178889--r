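test_that("pointwise t-map matches t.test and the summary-statistic formula", {
  set.seed(21)
  A <- matrix(rnorm(9 * 12, 50, 4), 9, 12)
  B <- matrix(rnorm(7 * 12, 48, 5), 7, 12)
  cfg <- perm_config(min_group_coverage = 0)
  sm <- pointwise_tmap(A, B, cfg)
  for (j in c(1, 5, 12)) {
    ht <- stats::t.test(A[, j], B[, j])
    expect_equal(sm$t[j], unname(ht$statistic), tolerance = 1e-12)
    expect_equal(sm$p[j], ht$p.value, tolerance = 1e-12)
    expect_equal(sm$df[j], unname(ht$parameter), tolerance = 1e-9)
    w <- welch_t_from_summary(
      list(n = 9, mean = mean(A[, j]), sd = sd(A[, j])),
      list(n = 7, mean = mean(B[, j]), sd = sd(B[, j])))
    expect_equal(sm$t[j], w$t, tolerance = 1e-12)
  }
  # pooled-variance option agrees with var.equal t.test
  smp <- pointwise_tmap(A, B, perm_config(min_group_coverage = 0,
                                          var_equal = TRUE))
  ht <- stats::t.test(A[, 3], B[, 3], var.equal = TRUE)
  expect_equal(smp$t[3], unname(ht$statistic), tolerance = 1e-12)
})

test_that("t-map is antisymmetric, null on identical groups, and masked by coverage", {
  set.seed(4)
  A <- matrix(rnorm(6 * 10, 10), 6, 10)
  B <- matrix(rnorm(6 * 10, 10), 6, 10)
  cfg <- perm_config(min_group_coverage = 0)
  expect_equal(pointwise_tmap(A, B, cfg)$t,
               -pointwise_tmap(B, A, cfg)$t, tolerance = 1e-12)
  sm0 <- pointwise_tmap(A, A, cfg)
  expect_true(all(sm0$t == 0))
  expect_true(all(sm0$p == 1))
  # a point constant in both groups has zero variance: t = 0 with warning
  Ac <- A; Bc <- B; Ac[, 2] <- 7; Bc[, 2] <- 7
  expect_warning(smz <- pointwise_tmap(Ac, Bc, cfg), "zero variance")
  expect_equal(smz$t[2], 0)
  expect_equal(smz$n_zero_var, 1)
  # coverage: a pixel active in only 2 of 6 subjects of one group is masked
  A2 <- A; A2[1:4, 7] <- 0
  sm <- pointwise_tmap(A2, B, perm_config(min_group_coverage = 0.5))
  expect_false(sm$mask[7])
  expect_true(is.na(sm$t[7]))
})

test_that("cluster formation equals flood-fill on the super-threshold mask", {
  set.seed(11)
  for (rep in 1:6) {
    dims <- c(9, 14)
    t_vals <- rnorm(prod(dims)) * 3
    p_vals <- 2 * pt(-abs(t_vals), df = 30)
    sm <- structure(list(t = t_vals, p = p_vals,
                         df = rep(30, prod(dims)),
                         mask = rep(TRUE, prod(dims)), dim = dims,
                         n_a = 5, n_b = 5, n_zero_var = 0),
                    class = "stat_map")
    cfg <- perm_config(cluster_forming_p = 0.1, cluster_alpha = 0.2)
    cl <- form_clusters(sm, cfg)
    members <- attr(cl, "members")
    # oracle: flood-fill per sign
    got <- list()
    for (sgn in c(1, -1)) {
      super <- matrix(p_vals < 0.1 & sign(t_vals) == sgn, dims[1], dims[2])
      lab <- bfs_label(super, 8)
      got <- c(got, label_partition(lab))
    }
    expect_setequal(lapply(members, sort), got)
    # masses are the sum of |t| over members
    for (i in seq_len(nrow(cl))) {
      expect_equal(cl$mass[i], sum(abs(t_vals[members[[i]]])))
      expect_gte(cl$mass[i], cl$max_t[i])
    }
    expect_equal(cl$mass, sort(cl$mass, decreasing = TRUE))
  }
})

test_that("degenerate cluster inputs behave", {
  t_vals <- rep(0.1, 12)
  sm <- structure(list(t = t_vals, p = rep(0.9, 12), df = rep(10, 12),
                       mask = rep(TRUE, 12), dim = c(3L, 4L),
                       n_a = 4, n_b = 4, n_zero_var = 0),
                  class = "stat_map")
  expect_equal(nrow(form_clusters(sm, perm_config())), 0)
  # one isolated super-threshold pixel: a singleton cluster of mass |t|
  sm$t[5] <- 4.2; sm$p[5] <- 0.002
  cl <- form_clusters(sm, perm_config())
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 1L)
  expect_equal(cl$mass, 4.2)
})

test_that("Monte Carlo permutation null is deterministic and sized as configured", {
  set.seed(2)
  x <- rbind(matrix(rnorm(8 * 10, 1), 8, 10), matrix(rnorm(8 * 10, 1), 8, 10))
  labs <- rep(c("a", "b"), each = 8)
  cfg <- perm_config(n_perm = 120, seed = 77, method = "monte_carlo",
                     min_group_coverage = 0)
  n1 <- permutation_null(x, labs, cfg)
  n2 <- permutation_null(x, labs, cfg)
  expect_identical(n1, n2)
  expect_length(n1, 120)
  expect_equal(perm_config()$n_perm, 1000L)
  # tiny inputs: fewer distinct relabelings than n_perm warns
  xs <- x[c(1:3, 9:11), ]; ls <- rep(c("a", "b"), each = 3)
  expect_warning(
    permutation_null(xs, ls, perm_config(n_perm = 100, seed = 1,
                                         method = "monte_carlo",
                                         min_group_coverage = 0)),
    "distinct relabelings")
})

test_that("exhaustive null matches the brute-force enumeration oracle exactly", {
  set.seed(33)
  x <- rbind(matrix(rnorm(5 * 8, 2, 1), 5, 8),
             matrix(rnorm(3 * 8, 2, 1), 3, 8))
  x[1:5, 3:4] <- x[1:5, 3:4] + 2.5    # make a real cluster likely
  labs <- rep(c("a", "b"), c(5, 3))
  cfg <- perm_config(n_perm = 1000, seed = 5, min_group_coverage = 0)
  null <- permutation_null(x, labs, cfg)   # auto -> exhaustive (56 <= 1000)
  expect_identical(attr(null, "method"), "exhaustive")
  oracle <- exhaustive_null_oracle(x, 5)
  expect_length(null, 56)
  expect_equal(sort(as.numeric(null)), sort(oracle), tolerance = 1e-9)
  # cluster p-values equal the exact enumeration proportion
  ct <- cluster_test(x[1:5, ], x[6:8, ], cfg)
  expect_identical(ct$method, "exhaustive")
  for (i in seq_len(nrow(ct$clusters))) {
    obs <- ct$clusters$mass[i]
    expect_equal(ct$clusters$p_corrected[i], mean(oracle >= obs),
                 tolerance = 1e-9)
  }
})

test_that("corrected p-values respect their floor and the alpha rule", {
  set.seed(14)
  a <- matrix(rnorm(10 * 30, 1), 10, 30); a[, 10:14] <- a[, 10:14] + 3
  b <- matrix(rnorm(10 * 30, 1), 10, 30)
  cfg <- perm_config(n_perm = 99, seed = 3, method = "monte_carlo",
                     min_group_coverage = 0)
  ct <- cluster_test(a, b, cfg)
  expect_true(all(ct$clusters$p_corrected >= 1 / 100))
  expect_identical(ct$clusters$significant, ct$clusters$p_corrected <= 0.05)
})

test_that("results are invariant to subject order within groups", {
  set.seed(6)
  a <- matrix(rnorm(8 * 20, 5), 8, 20); b <- matrix(rnorm(6 * 20, 5), 6, 20)
  cfg <- perm_config(n_perm = 60, seed = 12, method = "monte_carlo",
                     min_group_coverage = 0)
  r1 <- cluster_test(a, b, cfg)
  r2 <- cluster_test(a[sample(8), ], b[sample(6), ], cfg)
  expect_equal(r1$stat_map$t, r2$stat_map$t, tolerance = 1e-12)
  expect_equal(tidy(r1)$mass, tidy(r2)$mass, tolerance = 1e-12)
  # the exhaustive null enumerates all relabelings, so its multiset of max
  # statistics is exactly order-invariant
  a5 <- a[1:5, 1:8]; b3 <- b[1:3, 1:8]
  cfg_ex <- perm_config(min_group_coverage = 0, method = "exhaustive")
  n1 <- permutation_null(rbind(a5, b3), rep(c("a", "b"), c(5, 3)), cfg_ex)
  n2 <- permutation_null(rbind(a5[sample(5), ], b3[sample(3), ]),
                         rep(c("a", "b"), c(5, 3)), cfg_ex)
  expect_equal(sort(as.numeric(n1)), sort(as.numeric(n2)), tolerance = 1e-12)
})

test_that("cluster mass grows monotonically with the injected effect size", {
  set.seed(18)
  grid <- standard_grid(30, 15)
  tpl <- foot_template(grid)
  noise_a <- array(rnorm(12 * prod(grid$dim), 0, 0.1), c(12, prod(grid$dim)))
  noise_b <- array(rnorm(12 * prod(grid$dim), 0, 0.1), c(12, prod(grid$dim)))
  mask <- region_preset("calcaneus", grid)
  support <- as.vector(tpl > 0)
  masses <- vapply(c(0.1, 0.2, 0.35, 0.5), function(delta) {
    tpl_a <- inject_regional_effect(tpl, "calcaneus", delta, grid)
    a <- (rep(1, 12) %o% as.vector(tpl_a)) + noise_a
    b <- (rep(1, 12) %o% as.vector(tpl)) + noise_b
    a[, !support] <- 0; b[, !support] <- 0
    attr(a, "map_dim") <- grid$dim; attr(b, "map_dim") <- grid$dim
    sm <- pointwise_tmap(a, b, perm_config())
    cl <- form_clusters(sm, perm_config())
    if (nrow(cl) == 0) 0 else max(cl$mass)
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("max_t cluster statistic is available behind the config switch", {
  set.seed(9)
  a <- matrix(rnorm(8 * 15, 3), 8, 15); a[, 4:6] <- a[, 4:6] + 3
  b <- matrix(rnorm(8 * 15, 3), 8, 15)
  cfg <- perm_config(n_perm = 50, seed = 2, method = "monte_carlo",
                     min_group_coverage = 0, cluster_stat = "max_t")
  ct <- cluster_test(a, b, cfg)
  expect_true(all(ct$clusters$max_t <= ct$clusters$mass + 1e-12))
  expect_s3_class(tidy(ct), "tbl_df")
  expect_equal(glance(ct)$cluster_stat, "max_t")
})
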