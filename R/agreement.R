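#' Paired sensor-vs-measured sample
#'
#' @param sensor numeric vector of sensor-estimated values.
#' @param measured numeric vector of manually measured values, same length.
#' @param units optional units tag (e.g. `"m"`).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(sensor, measured, units = NULL) {
  sensor <- as.numeric(sensor); measured <- as.numeric(measured)
  if (length(sensor) != length(measured))
    stop("`sensor` and `measured` must have equal length")
  if (length(sensor) < 2L) stop("need at least 2 pairs")
  if (!all(is.finite(sensor)) || !all(is.finite(measured)))
    stop("all paired values must be finite")
  structure(list(x = sensor, y = measured, n = length(sensor), units = units),
            class = "paired_sample")
}

as_paired <- function(pairs) {
  if (inherits(pairs, "paired_sample")) return(pairs)
  stop("expected a paired_sample; see paired_sample()")
}

#' Coefficient of determination for sensor-vs-measured agreement
#'
#' `r2 = 1 - SSres / SStot` with `SSres = sum((y_i - x_i)^2)` (measured
#' minus sensor). The reference mean in `SStot = sum((y_i - mean)^2)` is
#' the mean of the *sensor* estimates by default — the convention under
#' which the validation battery is defined here — while
#' `denominator = "measured-mean"` gives the conventional regression
#' form centered on the measured mean.
#'
#' @param pairs a [paired_sample()].
#' @param denominator `"sensor-mean"` (default) or `"measured-mean"`.
#' @return The r-squared value.
#' @export
r_squared <- function(pairs, denominator = c("sensor-mean", "measured-mean")) {
  p <- as_paired(pairs)
  denominator <- match.arg(denominator)
  center <- if (denominator == "sensor-mean") mean(p$x) else mean(p$y)
  ss_tot <- sum((p$y - center)^2)
  if (ss_tot == 0)
    stop("zero total sum of squares: measured values carry no spread about the reference mean")
  1 - sum((p$y - p$x)^2) / ss_tot
}

#' Error metrics for paired differences
#'
#' Differences are `d = sensor - measured`, so a negative bias means the
#' sensor underestimates. Returns RMSE (`sqrt(mean(d^2))`), MAE
#' (`mean(abs(d))`), bias (`mean(d)`) and the sample standard deviation
#' of the differences (`n - 1` denominator).
#'
#' @param pairs a [paired_sample()].
#' @return List with `rmse`, `mae`, `bias`, `s_d` and `n`.
#' @export
error_metrics <- function(pairs) {
  p <- as_paired(pairs)
  d <- p$x - p$y
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)), bias = mean(d),
       s_d = stats::sd(d), n = p$n)
}

#' Confidence interval for the mean sensor-measured difference
#'
#' Paired-t interval `dbar +/- t*(1 - alpha/2, n - 1) * s_d / sqrt(n)`.
#'
#' @param pairs a [paired_sample()].
#' @param confidence confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
mean_difference_ci <- function(pairs, confidence = 0.95) {
  p <- as_paired(pairs)
  d <- p$x - p$y
  ci_from_summary(mean(d), stats::sd(d), p$n, confidence)
}

#' Paired-t interval from summary statistics
#'
#' The same interval as [mean_difference_ci()] computed from a printed
#' (bias, sd of differences, n) triple rather than raw pairs — useful
#' for reconstructing reported intervals from summary tables.
#'
#' @param dbar mean difference (bias).
#' @param s_d standard deviation of the differences.
#' @param n number of pairs.
#' @param confidence confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
ci_from_summary <- function(dbar, s_d, n, confidence = 0.95) {
  if (n < 2) stop("need n >= 2")
  if (s_d < 0) stop("`s_d` must be non-negative")
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  c(lower = dbar - tcrit * s_d / sqrt(n), upper = dbar + tcrit * s_d / sqrt(n))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 rho sx sy / (sx^2 + sy^2 + (mx - my)^2)` with population
#' (1/n) variances by default, the convention under which Lin's
#' estimator is defined; `variance = "sample"` uses n - 1.
#'
#' @param pairs a [paired_sample()].
#' @param variance `"population"` (default) or `"sample"`.
#' @return The CCC, in `[-1, 1]`.
#' @export
concordance_ccc <- function(pairs, variance = c("population", "sample")) {
  p <- as_paired(pairs)
  variance <- match.arg(variance)
  mx <- mean(p$x); my <- mean(p$y)
  denomn <- if (variance == "population") p$n else p$n - 1L
  vx <- sum((p$x - mx)^2) / denomn
  vy <- sum((p$y - my)^2) / denomn
  if (vx == 0 || vy == 0) stop("zero variance: CCC undefined")
  cxy <- sum((p$x - mx) * (p$y - my)) / denomn
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Paired t-test on sensor-measured differences
#'
#' `t = dbar / (s_d / sqrt(n))` with `n - 1` degrees of freedom;
#' the p-value is the two-sided tail probability of the t distribution.
#'
#' @param pairs a [paired_sample()].
#' @return List with `t`, `p`, `df`.
#' @export
paired_t_test <- function(pairs) {
  p <- as_paired(pairs)
  d <- p$x - p$y
  s_d <- stats::sd(d)
  if (s_d == 0) stop("zero-variance differences: t statistic undefined")
  t <- mean(d) / (s_d / sqrt(p$n))
  list(t = t, p = t_p_value(t, p$n - 1L), df = p$n - 1L)
}

#' Two-sided p-value of a t statistic
#' @param t observed t statistic.
#' @param df degrees of freedom.
#' @return Two-sided tail probability.
#' @export
t_p_value <- function(t, df) {
  2 * stats::pt(-abs(t), df = df)
}

#' Full sensor-vs-measured agreement report
#'
#' Computes the whole validation battery for one geometric feature:
#' group means and sds, r-squared, RMSE, MAE, bias, sd of differences,
#' the 95% paired-t confidence interval of the mean difference, Lin's
#' CCC, and the paired t statistic with its two-sided p-value. The
#' internal identity `RMSE^2 = bias^2 + ((n-1)/n) s_d^2` is asserted on
#' every report.
#'
#' @param pairs a [paired_sample()].
#' @param confidence CI confidence level, default 0.95.
#' @param metric optional label for printing (e.g. `"tree height"`).
#' @return An object of class `agreement_report` (a named list of all
#'   statistics, full precision).
#' @export
agreement_report <- function(pairs, confidence = 0.95, metric = NULL) {
  p <- as_paired(pairs)
  em <- error_metrics(p)
  perfect <- all(p$x == p$y)
  rep <- list(
    metric = metric, n = p$n, units = p$units,
    mean_sensor = mean(p$x), sd_sensor = stats::sd(p$x),
    mean_measured = mean(p$y), sd_measured = stats::sd(p$y),
    r_squared = if (perfect) 1 else r_squared(p),
    rmse = em$rmse, mae = em$mae, bias = em$bias, s_d = em$s_d,
    ci = if (perfect) c(lower = 0, upper = 0) else mean_difference_ci(p, confidence),
    ccc = if (perfect) 1 else concordance_ccc(p),
    confidence = confidence)
  if (perfect) {
    rep$t <- 0; rep$p_value <- 1; rep$df <- p$n - 1L
  } else {
    tt <- paired_t_test(p)
    rep$t <- tt$t; rep$p_value <- tt$p; rep$df <- tt$df
  }
  delta <- rep$rmse^2 - (rep$bias^2 + (p$n - 1) / p$n * rep$s_d^2)
  if (abs(delta) > 1e-9 * max(1, rep$rmse^2))
    stop("internal inconsistency: RMSE identity violated") # nocov
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  lab <- x$metric %||% "paired sample"
  u <- if (!is.null(x$units)) paste0(" (", x$units, ")") else ""
  cat(sprintf("Agreement report: %s%s, n = %d\n", lab, u, x$n))
  cat(sprintf("  Mean (sensor / measured): %.*f / %.*f\n",
              digits, x$mean_sensor, digits, x$mean_measured))
  cat(sprintf("  Sd   (sensor / measured): %.*f / %.*f\n",
              digits, x$sd_sensor, digits, x$sd_measured))
  cat(sprintf("  RMSE %.*f | MAE %.*f | bias %.*f\n",
              digits, x$rmse, digits, x$mae, digits, x$bias))
  cat(sprintf("  r^2 %.*f | CCC %.*f\n", digits, x$r_squared, digits, x$ccc))
  cat(sprintf("  t = %.*f (df %d), two-sided p = %.4f\n",
              digits, x$t, x$df, x$p_value))
  cat(sprintf("  %d%% CI of mean difference: (%.*f, %.*f)\n",
              round(100 * x$confidence), digits, x$ci[["lower"]],
              digits, x$ci[["upper"]]))
  invisible(x)
}
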