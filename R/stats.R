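#' Independent two-sample t-test
#'
#' Classic pooled-variance independent t-test (two-sided) by default;
#' Welch's unequal-variance form available by flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
group_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group must have n >= 2")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe-Glynn 1983) Z statistics into the omnibus K2 = Zs^2 + Zk^2,
#' referred to a chi-square distribution with 2 df.
#'
#' @param x numeric vector, n >= 20.
#' @return list with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("D'Agostino-Pearson test requires n >= 20 (got ", n, ")")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance")
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970) normalizing transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * aa)) -
             ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Adjust variables to a common age
#'
#' Within each group, fits `value ~ age` by least squares and replaces the
#' observed values with `value + slope * (target_age - age)`: the value each
#' donor would show at the target age under the group's linear age trend.
#' Adjustment is per-group by default so that a between-group age gap is not
#' transferred into the adjusted variables; set `by_group = NULL` for a
#' pooled adjustment.
#'
#' @param data data.frame containing `age`, the variables, and the grouping
#'   column.
#' @param variables character vector of column names to adjust.
#' @param target_age target age in years (default 65).
#' @param by_group name of the grouping column (default `"sex"`), or `NULL`.
#' @return `data` with the named columns replaced by adjusted values; the
#'   attribute `"age_slopes"` logs the fitted slopes per group and variable.
#' @export
age_adjust <- function(data, variables, target_age = 65, by_group = "sex") {
  stopifnot("age" %in% names(data), all(variables %in% names(data)))
  groups <- if (is.null(by_group)) list(all = seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[by_group]])
  slopes <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < 3) stop("group `", gname, "` has n < 3; cannot age-adjust")
    for (v in variables) {
      ok <- idx[is.finite(data[[v]][idx])]
      sl <- if (var(data$age[ok]) == 0) 0
            else unname(coef(lm(data[[v]][ok] ~ data$age[ok]))[2])
      data[[v]][ok] <- data[[v]][ok] + sl * (target_age - data$age[ok])
      slopes[[paste(gname, v, sep = ".")]] <- sl
    }
  }
  attr(data, "age_slopes") <- unlist(slopes)
  data
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with slope/intercept estimates,
#' R-squared, the two-sided slope p-value, residual SE and 95 percent
#' coefficient CIs.
#'
#' @param x,y numeric vectors (n >= 3 complete pairs, x not constant).
#' @return an object of class `linreg_result` (list).
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("linear_fit requires n >= 3")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ci <- confint(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x),
                 residual_se = sm$sigma,
                 ci_slope = unname(ci[2, ]),
                 ci_intercept = unname(ci[1, ])),
            class = "linreg_result")
}

#' Percent-of-mean difference
#'
#' The percent-difference convention used throughout the elevation tables:
#' `100 * (male - female) / ((male + female) / 2)`. With the published
#' elevations 3561 (female) and 4606 (male) this reproduces the printed
#' 25.6 percent.
#'
#' @param e_female,e_male positive elevations (same units).
#' @return percent difference (full precision; round to 1 decimal for
#'   display).
#' @export
pct_difference <- function(e_female, e_male) {
  if (any(c(e_female, e_male) <= 0))
    stop("pct_difference requires positive elevations")
  100 * (e_male - e_female) / ((e_male + e_female) / 2)
}

#' ANCOVA comparison of two regression lines
#'
#' Tests whether two groups share (1) a regression slope, via the F-test of
#' the group-by-x interaction, and (2) an elevation, via the F-test of the
#' group term in the common-slope model. Elevations are quantified by
#' shifting x by the midpoint of the pooled x range `(min + max) / 2`,
#' refitting per-group regressions, and reading off the intercepts with
#' their 95 percent CIs; the elevation difference (second group minus
#' first), its CI from the common-slope model group coefficient, and the
#' percent-of-mean difference are reported. Midpoint shifting changes the
#' intercepts but not the slopes or R-squared.
#'
#' @param x,y numeric vectors.
#' @param group a factor (or coercible) with exactly two levels; the first
#'   level plays the "female" role in the percent difference.
#' @return an object of class `ancova_result` (list; see fields in source).
#' @export
ancova_compare <- function(x, y, group) {
  ok <- is.finite(x) & is.finite(y) & !is.na(group)
  x <- x[ok]; y <- y[ok]; group <- droplevels(factor(group[ok]))
  if (nlevels(group) != 2) stop("ancova_compare requires exactly two groups")
  ns <- table(group)
  if (any(ns < 3)) stop("each group must have n >= 3")
  for (lv in levels(group))
    if (var(x[group == lv]) == 0)
      stop("group `", lv, "` has zero x-variance")

  fit_int <- lm(y ~ x * group)
  fit_cs <- lm(y ~ x + group)
  a_int <- anova(fit_cs, fit_int)
  slope_p <- a_int[2, "Pr(>F)"]
  elevation_p <- anova(fit_cs)["group", "Pr(>F)"]

  mid <- (min(x) + max(x)) / 2
  xs <- x - mid
  elev <- lapply(levels(group), function(lv) {
    f <- lm(y[group == lv] ~ xs[group == lv])
    ci <- confint(f)[1, ]
    c(elevation = unname(coef(f)[1]), lo = unname(ci[1]), hi = unname(ci[2]))
  })
  names(elev) <- levels(group)
  e1 <- unname(elev[[1]]["elevation"]); e2 <- unname(elev[[2]]["elevation"])

  cs_coef <- paste0("group", levels(group)[2])
  diff_ci <- confint(fit_cs)[cs_coef, ]

  structure(list(
    slope_p = slope_p,
    elevation_p = elevation_p,
    common_slope = unname(coef(fit_cs)["x"]),
    midpoint = mid,
    elevations = data.frame(group = levels(group),
                            elevation = c(e1, e2),
                            lo = c(elev[[1]]["lo"], elev[[2]]["lo"]),
                            hi = c(elev[[1]]["hi"], elev[[2]]["hi"]),
                            row.names = NULL),
    elevation_diff = unname(e2 - e1),
    elevation_diff_ci = unname(diff_ci),
    pct_diff = if (e1 > 0 && e2 > 0) pct_difference(e1, e2) else NA_real_,
    n = as.vector(ns)), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: slope-equality p = %.4g, elevation p = %.4g\n",
              x$slope_p, x$elevation_p))
  print(x$elevations, digits = 5)
  cat(sprintf("difference = %.4g (95%% CI %.4g to %.4g), %%diff = %.1f\n",
              x$elevation_diff, x$elevation_diff_ci[1], x$elevation_diff_ci[2],
              x$pct_diff))
  invisible(x)
}

#' Multivariable regression with VIF screening
#'
#' OLS of `y` on a set of predictors with unstandardized coefficients and 95
#' percent CIs, standardized betas (`B * SD(x) / SD(y)`), per-term p-values,
#' variance inflation factors (`VIF_j = 1 / (1 - R2_j)` from regressing each
#' predictor on the others; perfectly collinear terms get infinite VIF), and
#' adjusted R-squared. While any VIF exceeds `vif_cutoff`, the term with the
#' maximum VIF is removed and the model refit; removals are logged.
#'
#' @param y numeric response.
#' @param predictors data.frame of numeric predictors (categorical terms
#'   pre-coded, e.g. sex as 0/1).
#' @param vif_cutoff removal threshold (default 10).
#' @return an object of class `multivar_model`: list with `terms`
#'   (data.frame: term, b, lo, hi, std_beta, p, vif), `adj_r2`, `n`,
#'   `removed` (character vector removal log).
#' @export
multivariable_fit <- function(y, predictors, vif_cutoff = 10) {
  stopifnot(is.data.frame(predictors))
  ok <- is.finite(y) & complete.cases(predictors)
  y <- y[ok]; predictors <- predictors[ok, , drop = FALSE]
  if (length(y) <= ncol(predictors) + 1)
    stop("n must exceed number of predictors + 1")
  removed <- character()

  vif_of <- function(df) {
    if (ncol(df) == 1L) return(setNames(1, names(df)))
    vapply(names(df), function(v) {
      xv <- df[[v]]
      r2 <- summary(lm(xv ~ ., data = df[setdiff(names(df), v)]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  repeat {
    vifs <- vif_of(predictors)
    if (all(is.finite(vifs)) && max(vifs) <= vif_cutoff) break
    worst <- names(which.max(vifs))
    removed <- c(removed, sprintf("%s (VIF = %.3g)", worst, vifs[worst]))
    predictors <- predictors[setdiff(names(predictors), worst)]
    if (ncol(predictors) == 0L)
      stop("all predictors removed by the VIF loop (perfect collinearity)")
  }

  fit <- lm(y ~ ., data = predictors)
  sm <- summary(fit)
  ci <- confint(fit)
  terms <- names(predictors)
  b <- coef(fit)[terms]
  terms_df <- data.frame(
    term = terms,
    b = unname(b),
    lo = ci[terms, 1],
    hi = ci[terms, 2],
    std_beta = unname(b) * vapply(predictors, sd, numeric(1)) / sd(y),
    p = sm$coefficients[terms, 4],
    vif = unname(vif_of(predictors)[terms]),
    row.names = NULL)
  structure(list(terms = terms_df,
                 intercept = unname(coef(fit)[1]),
                 adj_r2 = sm$adj.r.squared,
                 n = length(y),
                 removed = removed),
            class = "multivar_model")
}

#' @export
print.multivar_model <- function(x, ...) {
  cat(sprintf("Multivariable OLS (n = %d, adj R2 = %.3f)\n", x$n, x$adj_r2))
  print(x$terms, digits = 4)
  if (length(x$removed))
    cat("removed by VIF loop:", paste(x$removed, collapse = "; "), "\n")
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure (the standard
#' test-retest reliability form), with the F-distribution confidence
#' interval of Shrout and Fleiss.
#'
#' @param ratings numeric matrix, subjects in rows (n >= 5), raters /
#'   repeats in columns (k >= 2), no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `lo`, `hi`, `n`, `k`.
#' @export
icc21 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("icc21 requires n >= 5 subjects and k >= 2 raters")
  if (anyNA(ratings)) stop("missing cells not allowed")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (den == 0) 1 else (msr - mse) / den

  alpha <- 1 - conf
  if (mse == 0 && msc <= mse) return(list(icc = 1, lo = 1, hi = 1, n = n, k = k))
  fj <- msc / mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * fj + b)^2 /
    (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lo = lo, hi = hi, n = n, k = k)
}
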