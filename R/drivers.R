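# Driver attribution: correlate bloom frequency with daily meteorology and
# annual nutrient usage, assign each lake its best-explaining factor, and
# summarize temperature-threshold bloom statistics.

#' Pearson correlation with a two-sided t-test
#'
#' Closed-form textbook Pearson r with `t = r * sqrt((n-2)/(1-r^2))` and a
#' two-sided p from the t distribution (n - 2 df). Degenerate inputs
#' (fewer than 3 pairs, or zero variance in either series) are marked
#' incomputable (`r = NA`).
#'
#' @param x,y numeric vectors of equal length (pairs with NA dropped).
#' @param method "pearson" (default) or "spearman" (ranks, same test).
#' @return list with `r`, `p_value`, `n`.
#' @export
cor_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Correlate daily bloom frequency with daily meteorology
#'
#' Same-day Pearson correlation (no lag by default; surface bloom formation
#' and break-up respond to weather within hours to days) between the
#' cloud-weighted daily frequency and air temperature, wind speed and
#' precipitation. Days without any valid observation carry no bloom
#' information and are excluded rather than treated as zero frequency.
#'
#' @param records daily detection records (`date`, `A_Bloom`, `A_valid`,
#'   `A_Lake`).
#' @param met meteorological series (`date`, `air_temperature`,
#'   `wind_speed`, `precipitation`).
#' @param lag days by which frequency is shifted relative to the weather
#'   (default 0; positive looks at weather `lag` days earlier).
#' @param method correlation type, see [cor_with_p()].
#' @return data.frame with one row per factor (`temperature`,
#'   `precipitation`, `wind`) and columns `factor`, `r`, `p_value`, `n`.
#' @export
daily_driver_correlation <- function(records, met, lag = 0L,
                                     method = "pearson") {
  obs <- records[records$A_valid > 0, , drop = FALSE]
  obs$freq <- daily_frequency(obs$A_Bloom, obs$A_valid, obs$A_Lake)
  met_dates <- as.integer(as.Date(met$date)) + as.integer(lag)
  idx <- match(as.integer(as.Date(obs$date)), met_dates)
  ok <- !is.na(idx)
  if (sum(ok) < 10) stop_config("need >= 10 matched observed days")
  obs <- obs[ok, , drop = FALSE]
  midx <- idx[ok]
  factors <- c(temperature = "air_temperature", precipitation = "precipitation",
               wind = "wind_speed")
  rows <- lapply(names(factors), function(f) {
    ct <- cor_with_p(obs$freq, met[[factors[[f]]]][midx], method = method)
    data.frame(factor = f, r = ct$r, p_value = ct$p_value, n = ct$n)
  })
  do.call(rbind, rows)
}

# Subset definitions over the ten N input categories (by position):
# fertilizer i-iv, manure v-viii, atmospheric ix-x, cropland i+ii+v,
# pasture iii+iv+vi+vii.
.N_SUBSETS <- list(
  total_n = 1:10,
  fertilizer_n_input = 1:4,
  manure_n = 5:8,
  atmospheric_n = 9:10,
  cropland_n = c(1, 2, 5),
  pasture_n = c(3, 4, 6, 7)
)

#' Aggregate the ten N input categories into the reported subsets
#'
#' @param nutrients data.frame containing the ten category columns named in
#'   [n_input_categories()].
#' @return data.frame with columns `total_n`, `fertilizer_n_input`,
#'   `manure_n`, `atmospheric_n`, `cropland_n`, `pasture_n`.
#' @export
n_input_subsets <- function(nutrients) {
  cats <- n_input_categories()
  missing <- setdiff(cats, names(nutrients))
  if (length(missing)) {
    stop_format("nutrient table is missing categories: ",
                paste(missing, collapse = ", "))
  }
  mat <- as.matrix(nutrients[, cats, drop = FALSE])
  if (any(mat < 0)) stop_format("N input categories must be non-negative")
  out <- lapply(.N_SUBSETS, function(ix) rowSums(mat[, ix, drop = FALSE]))
  as.data.frame(out)
}

#' Correlate annual bloom frequency with nutrient quantities
#'
#' Pearson correlation over the overlapping years between annual bloom
#' frequency and each of: N fertilizer, P fertilizer, total anthropogenic N
#' input, and the fertilizer / manure / atmospheric / cropland / pasture
#' subsets of the ten categories. Total N is the exact sum of the ten
#' categories (verified by construction in [n_input_subsets()]).
#'
#' @param annual data.frame with `bloom_year` and `annual_frequency`.
#' @param nutrients data.frame from [generate_nutrient_series()] (or same
#'   layout).
#' @param min_years minimum overlapping years with defined frequency
#'   (default 5).
#' @return data.frame with columns `quantity`, `r`, `p_value`, `n`.
#' @export
annual_nutrient_correlation <- function(annual, nutrients, min_years = 5L) {
  ann <- annual[!is.na(annual$annual_frequency), , drop = FALSE]
  idx <- match(ann$bloom_year, nutrients$year)
  ok <- !is.na(idx)
  if (sum(ok) < min_years) {
    stop_config("need >= ", min_years, " overlapping years")
  }
  ann <- ann[ok, , drop = FALSE]
  nut <- nutrients[idx[ok], , drop = FALSE]
  quantities <- cbind(nut[, c("fertilizer_N", "fertilizer_P")],
                      n_input_subsets(nut))
  rows <- lapply(names(quantities), function(q) {
    ct <- cor_with_p(ann$annual_frequency, quantities[[q]])
    data.frame(quantity = q, r = ct$r, p_value = ct$p_value, n = ct$n)
  })
  do.call(rbind, rows)
}

#' Assign the best-explaining factor to a lake
#'
#' Among factors significantly correlated with bloom frequency
#' (`p < alpha`), picks the one with the largest absolute correlation
#' (wind and precipitation act negatively, so magnitude is what matters);
#' ties are broken by a fixed factor ordering. A lake with no significant
#' factor is labeled `"others"`.
#'
#' @param correlations data.frame with columns `factor`, `r`, `p_value`
#'   (e.g. [daily_driver_correlation()] rows plus nutrient rows named
#'   `n_fertilizer` / `p_fertilizer`).
#' @param alpha significance level.
#' @param order tie-break factor ordering.
#' @return list with `best_factor` and the input `correlations`.
#' @export
assign_best_factor <- function(correlations, alpha = 0.05,
                               order = c("temperature", "precipitation",
                                         "wind", "n_fertilizer",
                                         "p_fertilizer")) {
  if (is.null(correlations) || nrow(correlations) == 0) {
    stop_config("at least one factor must be attempted")
  }
  cand <- correlations[!is.na(correlations$r) &
                         !is.na(correlations$p_value) &
                         correlations$p_value < alpha, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(best_factor = "others", correlations = correlations))
  }
  rank_in_order <- match(cand$factor, order)
  rank_in_order[is.na(rank_in_order)] <- length(order) + 1L
  ord <- order(-abs(cand$r), rank_in_order)
  list(best_factor = cand$factor[ord[1]], correlations = correlations)
}

#' Fractions of bloom events above/below air-temperature thresholds
#'
#' @param temperatures same-day air temperature (deg C) of every bloom event
#'   (lake-day with positive detected bloom area).
#' @param warm,cool thresholds (default 20 and 16 deg C).
#' @return list with `frac_above_warm` (T > warm), `frac_below_cool`
#'   (T <= cool) and `n_events`; fractions are NA when there are no events.
#' @export
temperature_threshold_stats <- function(temperatures, warm = 20, cool = 16) {
  temperatures <- temperatures[!is.na(temperatures)]
  n <- length(temperatures)
  if (n == 0) {
    return(list(frac_above_warm = NA_real_, frac_below_cool = NA_real_,
                n_events = 0L))
  }
  list(frac_above_warm = mean(temperatures > warm),
       frac_below_cool = mean(temperatures <= cool),
       n_events = n)
}
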