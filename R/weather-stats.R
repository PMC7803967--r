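# Weather-count regression: quadratic detrending of log counts and of the
# twelve weather factors, a no-intercept multivariable least-squares fit
# of the detrended log count on the detrended factors, the HT3 time test,
# and a table-shaped report.

#' Encode a circular wind direction as EW/NS components
#'
#' Degrees-scaled sine/cosine decomposition of the prevailing wind
#' direction (0 = north, 90 = east): `EW = sin(theta) * 90`,
#' `NS = cos(theta) * 90`.
#'
#' @param direction_deg direction(s) in `[0, 360)`.
#' @param scale degree scaling of the components (default 90).
#' @return matrix with columns `ew` and `ns`.
#' @export
wind_components <- function(direction_deg, scale = 90) {
  assert_that(all(direction_deg >= 0 & direction_deg < 360),
              "direction must be in [0, 360)")
  th <- direction_deg * pi / 180
  cbind(ew = sin(th) * scale, ns = cos(th) * scale)
}

#' Quadratic detrending
#'
#' OLS fit of a series on `{1, t, t^2}`; the residuals are the detrended
#' series, orthogonal to the polynomial basis by the normal equations.
#'
#' @param values numeric series.
#' @param t_index time index (default `1..n`); needs n >= 4 and at least
#'   3 distinct values.
#' @return list with `coefficients` (`c(a0, a1, a2)`), `fitted`, and
#'   `residuals`.
#' @export
detrend <- function(values, t_index = seq_along(values)) {
  n <- length(values)
  assert_that(n >= 4, "need n >= 4 to fit a quadratic trend")
  X <- cbind(1, t_index, t_index^2)
  assert_that(qr(X)$rank == 3, "rank-deficient trend design (constant t?)")
  fit <- stats::lm.fit(X, values)
  list(coefficients = stats::setNames(unname(fit$coefficients),
                                      c("a0", "a1", "a2")),
       fitted = as.numeric(X %*% fit$coefficients),
       residuals = values - as.numeric(X %*% fit$coefficients))
}

#' HT3: does time influence the count-weather relationship?
#'
#' Fits the log count on the twelve weather factors plus a linear time
#' term (with intercept) and reports the two-tailed t-test on the time
#' coefficient. A significant result motivates detrending before the main
#' regression.
#'
#' @param ln_counts numeric log counts.
#' @param weather data.frame (or matrix) of the twelve factor columns.
#' @param t_index time index.
#' @param alpha significance level for the decision flag.
#' @return list with `statistic`, `p_value`, `significant`, `degenerate`
#'   (non-finite t under a perfect fit).
#' @export
ht3_time_test <- function(ln_counts, weather, t_index = seq_along(ln_counts),
                          alpha = 0.05) {
  X <- cbind(intercept = 1, as.matrix(weather), time = t_index)
  assert_that(qr(X)$rank == ncol(X), "collinear design in HT3")
  fit <- stats::lm.fit(X, ln_counts)
  df <- length(ln_counts) - ncol(X)
  assert_that(df > 0, "not enough observations for HT3")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_t <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  est <- unname(fit$coefficients["time"])
  if (se_t == 0 || !is.finite(est / se_t)) {
    return(list(statistic = NA_real_, p_value = 0, significant = TRUE,
                degenerate = TRUE, estimate = est))
  }
  tval <- est / se_t
  p <- 2 * stats::pt(-abs(tval), df)
  list(statistic = tval, p_value = p, significant = p < alpha,
       degenerate = FALSE, estimate = est)
}

#' Fit the detrended count-weather regression
#'
#' No-intercept least squares of the detrended log count on the detrended
#' factors (the detrended variables are orthogonal to the quadratic time
#' basis by construction, so no intercept is identified). Reports
#' per-coefficient two-tailed t-tests, R-squared, and the overall F-test,
#' with significance marks at 0.05 and 0.10.
#'
#' @param response detrended log counts.
#' @param design data.frame or matrix of detrended factors (n x p).
#' @param intercept add an intercept column (off by default).
#' @return list of class `regression_report`: `coefficients` data.frame
#'   (`factor`, `estimate`, `t`, `p_value`, `mark`), `r_squared`,
#'   `f_statistic`, `f_p_value`, `n`, `fitted`, `residuals`,
#'   `condition_number`.
#' @export
fit_regression <- function(response, design, intercept = FALSE) {
  X <- as.matrix(design)
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  assert_that(length(response) == n, "response length must match the design")
  assert_that(n > p, "need more observations than factors")
  qrX <- qr(X)
  if (qrX$rank < p) {
    sv <- svd(X, nu = 0, nv = 0)$d
    stop_ew(sprintf("singular design matrix (condition number %.3g)",
                    sv[1] / max(sv[length(sv)], .Machine$double.xmin)))
  }
  beta <- qr.coef(qrX, response)
  fitted <- as.numeric(X %*% beta)
  resid <- response - fitted
  rss <- sum(resid^2)
  tss <- sum(response^2)   # uncentered: the response is detrended (mean ~ 0)
  df <- n - p
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tval <- ifelse(se > 0, beta / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[is.na(tval)] <- NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else 0
  fstat <- if (rss > 0) ((tss - rss) / p) / sigma2 else Inf
  fp <- if (is.finite(fstat)) stats::pf(fstat, p, df, lower.tail = FALSE) else 0
  mark <- ifelse(is.na(pval), "", ifelse(pval < 0.05, "*",
                 ifelse(pval < 0.10, "**", "")))
  sv <- svd(X, nu = 0, nv = 0)$d
  structure(list(
    coefficients = data.frame(factor = colnames(X), estimate = unname(beta),
                              t = unname(tval), p_value = unname(pval),
                              mark = unname(mark), row.names = NULL),
    r_squared = r2, f_statistic = fstat, f_p_value = fp, n = n,
    fitted = fitted, residuals = resid,
    condition_number = sv[1] / sv[length(sv)]),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("Multivariable linear regression (detrended)\n")
  cat(sprintf("  n = %d   R^2 = %.3f   F p-value = %.4g\n",
              x$n, x$r_squared, x$f_p_value))
  df <- x$coefficients
  df$estimate <- sprintf("% .4f", df$estimate)
  df$p_value <- sprintf("%.3f", df$p_value)
  print(df[, c("factor", "estimate", "p_value", "mark")], row.names = FALSE)
  cat("  * p < 0.05 (significant)   ** p < 0.10 (marginal)\n")
  invisible(x)
}

#' Full detrended weather regression pipeline
#'
#' Detrends the log counts and each factor with a quadratic-in-time fit,
#' fits the no-intercept regression, and returns the report together with
#' the detrend fits and the HT3 test on the undetrended data.
#'
#' @param weather data.frame from [simulate_weather()] (or a real table
#'   with the same columns): `date`, the twelve factors, and a count
#'   column.
#' @param count_col name of the count column.
#' @param factors factor column names (default the standard twelve).
#' @return list with `report`, `ht3`, `detrend_y`, `detrend_x`,
#'   `response`, `design`.
#' @export
weather_regression <- function(weather, count_col = "count_all",
                               factors = weather_factor_names()) {
  assert_that(all(factors %in% names(weather)),
              "missing weather factor columns")
  y <- weather[[count_col]]
  assert_that(all(y > 0), "counts must be > 0 before taking logs")
  n <- nrow(weather)
  assert_that(n >= length(factors) + 3, "too few days for the regression")
  lny <- log(y)
  tt <- seq_len(n)
  dy <- detrend(lny, tt)
  dx <- lapply(factors, function(f) detrend(weather[[f]], tt))
  names(dx) <- factors
  design <- vapply(dx, `[[`, numeric(n), "residuals")
  report <- fit_regression(dy$residuals, design)
  ht3 <- ht3_time_test(lny, weather[factors], tt)
  list(report = report, ht3 = ht3, detrend_y = dy, detrend_x = dx,
       response = dy$residuals, design = design)
}

#' Write a table-shaped regression report
#'
#' @param result a [weather_regression()] result.
#' @param path output file (markdown).
#' @return `path`, invisibly.
#' @export
write_regression_report <- function(result, path) {
  rep <- result$report
  lines <- c(
    "# Multivariable linear regression analysis", "",
    "## Overall model fit", "",
    sprintf("- Number of observations: %d", rep$n),
    sprintf("- R^2: %.3f", rep$r_squared),
    sprintf("- p-value (F-test): %.4g", rep$f_p_value),
    sprintf("- HT3 time-influence p-value: %.4g", result$ht3$p_value), "",
    "## Parameter estimates", "",
    "| Independent variable | Coefficient | p-value (t-test) | |",
    "|---|---|---|---|",
    sprintf("| %s | %.4f | %.3f | %s |", rep$coefficients$factor,
            rep$coefficients$estimate, rep$coefficients$p_value,
            rep$coefficients$mark),
    "",
    "`*` p < 0.05 (statistically significant); `**` p < 0.10 (marginally significant).")
  writeLines(lines, path)
  invisible(path)
}
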