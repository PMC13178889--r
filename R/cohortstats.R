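#' Welch t-test from group summary statistics
#'
#' Unpaired two-sample t-test computed directly from printed group
#' summaries: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. With
#' both SDs zero and equal means, returns t = 0, p = 1.
#'
#' @param a,b Summary statistics: lists/rows with `n` (>= 2), `mean`, `sd`
#'   (>= 0).
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_from_summary(list(n = 68, mean = 34.5, sd = 14.9),
#'                      list(n = 24, mean = 33.7, sd = 14.4))
welch_t_from_summary <- function(a, b) {
  check_summary(a); check_summary(b)
  se2 <- a$sd^2 / a$n + b$sd^2 / b$n
  if (se2 == 0) {
    if (a$mean == b$mean) return(tibble(t = 0, df = a$n + b$n - 2, p = 1))
    abort("zero variance in both groups with unequal means")
  }
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

check_summary <- function(s) {
  if (is.null(s$n) || s$n < 2) abort("summary statistics need n >= 2")
  if (is.null(s$sd) || s$sd < 0) abort("summary statistics need sd >= 0")
  invisible(s)
}

#' Pooled-SD Cohen's d from group summary statistics
#'
#' `d = (m1 - m2) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param a,b Summary statistics (`n`, `mean`, `sd`).
#' @return Cohen's d (scalar).
#' @export
#' @examples
#' pooled_cohens_d_from_summary(list(n = 68, mean = 0.702, sd = 0.06),
#'                              list(n = 24, mean = 0.724, sd = 0.063))
pooled_cohens_d_from_summary <- function(a, b) {
  check_summary(a); check_summary(b)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) abort("pooled variance is zero; Cohen's d undefined")
  (a$mean - b$mean) / sqrt(sp2)
}

#' Confidence interval for a group mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param s Summary statistics (`n`, `mean`, `sd`).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
mean_ci <- function(s, level = 0.95) {
  check_summary(s)
  half <- qt((1 + level) / 2, s$n - 1) * s$sd / sqrt(s$n)
  c(lower = s$mean - half, upper = s$mean + half)
}

#' Two-group comparison table of scalar parameters
#'
#' For each requested parameter column, computes per-group n/mean/SD and
#' 95% CI, the Welch t-test, and pooled-SD Cohen's d, mirroring the layout
#' of a standard participant-characteristics table. Group A (the first
#' level) minus group B defines the sign. No multiple-comparison correction
#' is applied; significance flags are given at .05 and .01.
#'
#' @param data Data frame with a `sex` column (or the column named in
#'   `group`) plus the parameter columns.
#' @param vars Character vector of parameter column names.
#' @param group Grouping column name (two levels; default `"sex"`, with
#'   "female" first when present).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with one row per parameter: group means/SDs/CIs, `t`,
#'   `df`, `p`, `d`, `sig` ("", "*", "**").
#' @export
group_comparison_table <- function(data, vars, group = "sex",
                                   var_equal = FALSE) {
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) abort("grouping column must have exactly two levels")
  if (all(c("female", "male") %in% levels(g))) {
    g <- stats::relevel(g, "female")
  }
  lev <- levels(g)
  purrr::map(vars, function(v) {
    xa <- data[[v]][g == lev[1]]; xb <- data[[v]][g == lev[2]]
    sa <- list(n = length(xa), mean = mean(xa), sd = sd(xa))
    sb <- list(n = length(xb), mean = mean(xb), sd = sd(xb))
    tt <- if (var_equal) {
      ht <- stats::t.test(xa, xb, var.equal = TRUE)
      tibble(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
    } else {
      welch_t_from_summary(sa, sb)
    }
    cia <- mean_ci(sa); cib <- mean_ci(sb)
    tibble(
      parameter = v,
      n_a = sa$n, mean_a = sa$mean, sd_a = sa$sd,
      ci_lower_a = cia["lower"], ci_upper_a = cia["upper"],
      n_b = sb$n, mean_b = sb$mean, sd_b = sb$sd,
      ci_lower_b = cib["lower"], ci_upper_b = cib["upper"],
      t = tt$t, df = tt$df, p = tt$p,
      d = pooled_cohens_d_from_summary(sa, sb),
      sig = dplyr::case_when(tt$p < 0.01 ~ "**", tt$p < 0.05 ~ "*",
                             TRUE ~ "")
    )
  }) |> purrr::list_rbind()
}

#' Covariate-adjusted sex effect by multiple regression
#'
#' Fits an ordinary least squares model of a parameter on sex (coded
#' male = 0, female = 1), age, BMI, cadence, foot angle and walking speed,
#' and reports coefficient estimates with t statistics and variance
#' inflation factors (VIF = 1/(1 - R_j^2) from the auxiliary regression of
#' each predictor on the others).
#'
#' @param data Data frame containing the response and the predictor columns
#'   `sex` ("female"/"male" or 0/1), `age`, `bmi`, `cadence`, `foot_angle`,
#'   `speed`. No missing values.
#' @param response Name of the dependent parameter column.
#' @param predictors Predictor column names (defaults to the six above).
#' @return Object of class `sex_adjusted_fit`: list with `fit` (the `lm`),
#'   `coefficients` (tibble: term, estimate, std_error, statistic,
#'   p_value), `vif` (named vector), `response`.
#' @export
adjusted_sex_effect <- function(data, response,
                                predictors = c("sex", "age", "bmi",
                                               "cadence", "foot_angle",
                                               "speed")) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- data[, c(response, predictors)]
  if (anyNA(df)) abort("missing values are not allowed in the regression table")
  if ("sex" %in% predictors && !is.numeric(df$sex)) {
    df$sex <- as.numeric(df$sex == "female")  # male = 0, female = 1
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = df)
  if (fit$rank < length(predictors) + 1) {
    bad <- names(which(is.na(coef(fit))))
    abort(paste0("design matrix is rank deficient; collinear terms: ",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  vifs <- car::vif(fit)
  structure(list(
    fit = fit,
    coefficients = tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      statistic = sm[, 3], p_value = sm[, 4]
    ),
    vif = vifs,
    response = response
  ), class = "sex_adjusted_fit")
}

#' @export
print.sex_adjusted_fit <- function(x, ...) {
  cat(sprintf("<sex_adjusted_fit> response: %s\n", x$response))
  print(x$coefficients)
  cat("VIF:\n"); print(round(x$vif, 2))
  invisible(x)
}
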