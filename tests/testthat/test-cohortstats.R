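test_that("summary-statistic Welch test agrees with the raw-data computation", {
  a <- list(n = 14, mean = 52.3, sd = 6.1)
  b <- list(n = 9, mean = 47.8, sd = 8.4)
  xa <- sample_with_summary(a$n, a$mean, a$sd, seed = 1)
  xb <- sample_with_summary(b$n, b$mean, b$sd, seed = 2)
  ht <- stats::t.test(xa, xb)
  w <- welch_t_from_summary(a, b)
  expect_equal(w$t, unname(ht$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(ht$parameter), tolerance = 1e-9)
  expect_equal(w$p, ht$p.value, tolerance = 1e-9)
})

test_that("Welch t and Cohen's d are antisymmetric with sensible degenerate cases", {
  a <- list(n = 10, mean = 3, sd = 1); b <- list(n = 12, mean = 2.4, sd = 1.6)
  expect_equal(welch_t_from_summary(a, b)$t, -welch_t_from_summary(b, a)$t)
  expect_equal(pooled_cohens_d_from_summary(a, b),
               -pooled_cohens_d_from_summary(b, a))
  eq <- list(n = 8, mean = 5, sd = 2)
  expect_equal(welch_t_from_summary(eq, eq)$t, 0)
  expect_equal(pooled_cohens_d_from_summary(eq, eq), 0)
  z <- list(n = 5, mean = 1, sd = 0)
  expect_equal(welch_t_from_summary(z, z)$p, 1)
  expect_error(pooled_cohens_d_from_summary(z, z), "pooled variance")
  # equal n, equal sd: pooled SD equals that common SD exactly
  a2 <- list(n = 10, mean = 4, sd = 2.5); b2 <- list(n = 10, mean = 6, sd = 2.5)
  expect_equal(pooled_cohens_d_from_summary(a2, b2), (4 - 6) / 2.5)
})

test_that("for equal variances and sizes Welch equals the pooled t", {
  a <- list(n = 15, mean = 10, sd = 3); b <- list(n = 15, mean = 8, sd = 3)
  w <- welch_t_from_summary(a, b)
  sp <- sqrt(((a$n - 1) * 9 + (b$n - 1) * 9) / (a$n + b$n - 2))
  t_pooled <- (a$mean - b$mean) / (sp * sqrt(1 / a$n + 1 / b$n))
  expect_equal(w$t, t_pooled, tolerance = 1e-12)
  expect_equal(w$df, a$n + b$n - 2, tolerance = 1e-9)
})

test_that("mean CI has the t-interval form and nominal coverage", {
  ci <- mean_ci(list(n = 68, mean = 34.5, sd = 14.9))
  expect_equal(unname(ci["lower"]), 34.5 - qt(0.975, 67) * 14.9 / sqrt(68))
  ci0 <- mean_ci(list(n = 6, mean = 2, sd = 0))
  expect_equal(unname(ci0), c(2, 2))
  # Monte Carlo coverage of the 95% interval for normal samples
  set.seed(42)
  hits <- replicate(2000, {
    x <- rnorm(12, 7, 2)
    ci <- mean_ci(list(n = 12, mean = mean(x), sd = sd(x)))
    ci["lower"] <= 7 && 7 <= ci["upper"]
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("group comparison table reproduces its per-parameter pieces", {
  set.seed(10)
  df <- tibble::tibble(
    sex = rep(c("female", "male"), c(20, 12)),
    v1 = c(rnorm(20, 10, 2), rnorm(12, 12, 2)),
    v2 = rnorm(32)
  )
  tab <- group_comparison_table(df, c("v1", "v2"))
  expect_equal(nrow(tab), 2)
  ht <- stats::t.test(df$v1[df$sex == "female"], df$v1[df$sex == "male"])
  expect_equal(tab$t[1], unname(ht$statistic), tolerance = 1e-9)
  expect_equal(tab$mean_a[1], mean(df$v1[df$sex == "female"]))
  want_sig <- ifelse(tab$p < 0.01, "**", ifelse(tab$p < 0.05, "*", ""))
  expect_identical(tab$sig, want_sig)
})

test_that("adjusted sex effect uses the six predictors and sane VIFs", {
  set.seed(55)
  n <- 80
  df <- tibble::tibble(
    sex = rep(c("female", "male"), length.out = n),
    age = rnorm(n, 35, 10), bmi = rnorm(n, 22, 2),
    cadence = rnorm(n, 120, 8), foot_angle = rnorm(n, 4, 3),
    speed = rnorm(n, 1.4, 0.2)
  )
  df$y <- 5 + 2 * (df$sex == "female") + 0.1 * df$age + rnorm(n, 0, 1)
  fit <- adjusted_sex_effect(df, "y")
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "sex", "age", "bmi", "cadence",
                    "foot_angle", "speed"))
  # independent predictors: VIF near 1, and equal to 1/(1 - R^2_j)
  expect_true(all(fit$vif < 1.5))
  aux <- lm(age ~ sex + bmi + cadence + foot_angle + speed, data =
              dplyr::mutate(df, sex = as.numeric(sex == "female")))
  expect_equal(unname(fit$vif["age"]),
               1 / (1 - summary(aux)$r.squared), tolerance = 1e-9)
  # male = 0 / female = 1 coding: positive female shift recovered
  est <- fit$coefficients$estimate[fit$coefficients$term == "sex"]
  expect_gt(est, 1)
  expect_error(adjusted_sex_effect(dplyr::mutate(df, dup = speed), "y",
                                   predictors = c("speed", "dup")),
               "rank deficient|collinear")
})

test_that("regression recovers a known generating model across replicates", {
  truth <- c(`(Intercept)` = 2, sex = 1.5, age = 0.05, bmi = -0.2,
             cadence = 0.03, foot_angle = 0.1, speed = -1)
  set.seed(123)
  inside <- replicate(100, {
    n <- 60
    df <- tibble::tibble(
      sex = sample(c(0, 1), n, replace = TRUE),
      age = rnorm(n, 35, 10), bmi = rnorm(n, 22, 2),
      cadence = rnorm(n, 120, 8), foot_angle = rnorm(n, 4, 3),
      speed = rnorm(n, 1.4, 0.2)
    )
    mm <- cbind(1, as.matrix(df))
    df$y <- as.numeric(mm %*% truth) + rnorm(n)
    fit <- adjusted_sex_effect(df, "y")
    ci <- stats::confint(fit$fit)
    truth >= ci[, 1] & truth <= ci[, 2]
  })
  expect_gte(mean(inside), 0.93)
})
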