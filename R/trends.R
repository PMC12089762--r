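# Per-lake and global trend estimation of annual bloom metrics: eligibility
# filtering, OLS slopes with significance classes, relative growth rates,
# and the early-vs-late period comparison.

# Closed-form simple OLS of y on x with the slope's two-sided t-test.
# A perfect fit (zero residual variance) gets p = 0 for nonzero slopes and
# p = 1 for a flat line, which stats::lm leaves as NaN.
ols_slope <- function(x, y) {
  n <- length(x)
  if (n < 3) return(list(slope = NA_real_, intercept = NA_real_,
                         p_value = NA_real_, n = n))
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop_config("zero variance in the predictor (years)")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = intercept, p_value = p, n = n)
}

classify_trend <- function(slope, p_value, alpha = 0.05) {
  sig <- !is.na(p_value) && p_value < alpha
  if (slope > 0 || slope == 0) {           # slope = 0 ties take the Inc. branch
    if (sig && slope > 0) "Sig. Inc." else "Inc."
  } else {
    if (sig) "Sig. Dec." else "Dec."
  }
}

#' Lakes eligible for trend analysis
#'
#' A lake qualifies when blooms occurred in at least half of its observed
#' years (years with any valid observation): with 20 observed years this is
#' the study's "at least 10 years" rule; 7 of 14 qualifies, 9 of 20 does
#' not.
#'
#' @param metrics annual metrics table ([annual_metrics()] rows, possibly
#'   several lakes).
#' @return character vector of eligible lake ids (empty for an empty table).
#' @export
eligible_lakes <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) return(character(0))
  out <- vapply(split(metrics, metrics$lake), function(m) {
    n_obs <- sum(m$n_observations > 0)
    n_bloom <- sum(!is.na(m$annual_frequency))
    n_obs > 0 && 2L * n_bloom >= n_obs
  }, logical(1))
  names(out)[out]
}

#' Linear trend of one lake's annual metric
#'
#' Ordinary least-squares slope of the annual values on year, with the
#' slope's two-sided t-test (n - 2 df), classified into the four trend
#' classes "Sig. Inc.", "Inc.", "Sig. Dec.", "Dec." by sign and
#' `p < alpha`.
#'
#' @param years integer years.
#' @param values annual metric values (NA years are dropped).
#' @param lake lake id for the result row.
#' @param metric metric name ("frequency", "onset" or "persistence").
#' @param alpha significance level.
#' @return object of class `trend_result` (a one-row data.frame with `lake`,
#'   `metric`, `slope`, `p_value`, `n_years`, `trend_class`); slope and class
#'   are NA when fewer than 3 annual values exist.
#' @export
lake_trend <- function(years, values, lake = "lake", metric = "frequency",
                       alpha = 0.05) {
  keep <- !is.na(values) & !is.na(years)
  fit <- ols_slope(as.numeric(years[keep]), as.numeric(values[keep]))
  cls <- if (is.na(fit$slope)) NA_character_ else
    classify_trend(fit$slope, fit$p_value, alpha)
  structure(data.frame(lake = lake, metric = metric, slope = fit$slope,
                       p_value = fit$p_value, n_years = fit$n,
                       trend_class = cls, stringsAsFactors = FALSE),
            class = c("trend_result", "data.frame"))
}

#' Global median annual frequency series
#'
#' Per-year median of annual bloom frequency across the lakes that have a
#' defined annual value that year (bloom-affected lakes only contribute in
#' years they bloomed).
#'
#' @param metrics annual metrics table across lakes.
#' @return data.frame with `bloom_year` and `median_frequency`, sorted by
#'   year; years in which no lake has a defined value are dropped.
#' @export
global_median_series <- function(metrics) {
  ok <- metrics[!is.na(metrics$annual_frequency), , drop = FALSE]
  if (nrow(ok) == 0) {
    return(data.frame(bloom_year = integer(0), median_frequency = numeric(0)))
  }
  med <- tapply(ok$annual_frequency, ok$bloom_year, stats::median)
  data.frame(bloom_year = as.integer(names(med)),
             median_frequency = as.numeric(med), row.names = NULL)
}

#' Relative growth rate of a frequency series, in %/yr
#'
#' OLS slope of the series on year divided by the series' long-term mean,
#' times 100. The mean (rather than the first-year value) is used as the
#' base so the rate is robust to first-year noise; the rate is invariant to
#' rescaling the series by any positive constant.
#'
#' @param years integer years (>= 3).
#' @param values the series (e.g. yearly median frequencies).
#' @return list with `rate_percent_per_yr`, `slope`, `mean`, `p_value`, `n`.
#' @export
global_relative_rate <- function(years, values) {
  keep <- !is.na(values)
  years <- years[keep]; values <- values[keep]
  if (length(values) < 3) stop_config("need >= 3 yearly values")
  m <- mean(values)
  if (m == 0) stop_config("series mean is zero: relative rate undefined")
  fit <- ols_slope(as.numeric(years), as.numeric(values))
  list(rate_percent_per_yr = fit$slope / m * 100, slope = fit$slope,
       mean = m, p_value = fit$p_value, n = fit$n)
}

# Paired t-test in closed form so the all-zero-differences case is t = 0,
# p = 1 (stats::t.test refuses essentially-constant data).
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_config("paired samples differ in length")
  n <- length(a)
  if (n < 2) stop_config("paired t-test needs >= 2 pairs")
  d <- b - a
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
  } else {
    t <- md / (sd_d / sqrt(n))
  }
  list(t = t, p_value = 2 * stats::pt(-abs(t), df = n - 1),
       mean_difference = md, n = n)
}

# Per-lake relative growth rate over one period (>= 3 annual values and a
# positive period mean required; NA otherwise).
period_rate <- function(m, period) {
  sel <- m$bloom_year >= period[1] & m$bloom_year <= period[2] &
    !is.na(m$annual_frequency)
  if (sum(sel) < 3) return(NA_real_)
  v <- m$annual_frequency[sel]
  if (mean(v) == 0) return(NA_real_)
  ols_slope(as.numeric(m$bloom_year[sel]), v)$slope / mean(v) * 100
}

#' Compare per-lake relative growth rates between two periods
#'
#' For every lake with at least 3 annual values in each period, computes the
#' relative growth rate (period OLS slope / period mean frequency x 100) in
#' both periods and tests the paired difference across lakes with a matched
#' pair t-test. Optionally splits lakes at the median of their early-period
#' mean frequency to contrast rates of already-frequent vs less-affected
#' lakes ("deteriorating faster").
#'
#' @param metrics annual metrics table across lakes.
#' @param period_a,period_b length-2 inclusive year ranges.
#' @param split if `TRUE`, also return the period-b rate medians for lakes
#'   above/below the median early-period frequency.
#' @return list with `rates` (per-lake data.frame), `median_a`, `median_b`,
#'   `t`, `p_value`, `n`; `NULL` rates and NA test when no lake qualifies in
#'   both periods.
#' @export
period_comparison <- function(metrics, period_a = c(2003, 2015),
                              period_b = c(2016, 2022), split = FALSE) {
  by_lake <- split(metrics, metrics$lake)
  rows <- lapply(by_lake, function(m) {
    data.frame(lake = m$lake[1],
               rate_a = period_rate(m, period_a),
               rate_b = period_rate(m, period_b),
               early_mean = mean(m$annual_frequency[
                 m$bloom_year >= period_a[1] & m$bloom_year <= period_a[2]],
                 na.rm = TRUE))
  })
  rates <- do.call(rbind, rows)
  rates <- rates[!is.na(rates$rate_a) & !is.na(rates$rate_b), , drop = FALSE]
  if (nrow(rates) == 0) {
    return(list(rates = NULL, median_a = NA_real_, median_b = NA_real_,
                t = NA_real_, p_value = NA_real_, n = 0L))
  }
  if (nrow(rates) < 2) {
    return(list(rates = rates, median_a = stats::median(rates$rate_a),
                median_b = stats::median(rates$rate_b),
                t = NA_real_, p_value = NA_real_, n = nrow(rates)))
  }
  tt <- paired_t_test(rates$rate_a, rates$rate_b)
  out <- list(rates = rates, median_a = stats::median(rates$rate_a),
              median_b = stats::median(rates$rate_b),
              t = tt$t, p_value = tt$p_value, n = tt$n)
  if (split && nrow(rates) >= 4) {
    cut <- stats::median(rates$early_mean)
    hi <- rates$early_mean > cut
    out$split <- list(
      high_freq_rate_b = stats::median(rates$rate_b[hi]),
      low_freq_rate_b = stats::median(rates$rate_b[!hi]),
      n_high = sum(hi), n_low = sum(!hi))
  }
  out
}
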