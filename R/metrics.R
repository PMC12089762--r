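# Daily detections -> bloom statistics: cloud-weighted daily frequency,
# 15-day running mean, onset, persistence, annual frequency, with ice-season
# and hemisphere handling.

#' Cloud-weighted daily bloom frequency
#'
#' `frequency = (A_Bloom / A_valid) * (A_valid / A_Lake)^2
#'            = A_Bloom * A_valid / A_Lake^2`.
#' The squared valid-area fraction up-weights observations with low cloud
#' cover. Days with no valid observation return 0. All arguments are
#' vectorized.
#'
#' @param A_Bloom,A_valid,A_Lake areas in km2 with
#'   `0 <= A_Bloom <= A_valid <= A_Lake` and `A_Lake > 0`.
#' @return dimensionless frequency in \[0, 1\].
#' @export
daily_frequency <- function(A_Bloom, A_valid, A_Lake) {
  if (any(A_Lake <= 0)) stop_config("'A_Lake' must be positive")
  if (any(A_Bloom < 0 | A_Bloom > A_valid | A_valid > A_Lake)) {
    stop_config("need 0 <= A_Bloom <= A_valid <= A_Lake")
  }
  # factored so that full coverage (A_valid == A_Lake) reduces to the naive
  # ratio A_Bloom / A_Lake exactly, not just to rounding error
  ifelse(A_valid == 0, 0, (A_Bloom / A_Lake) * (A_valid / A_Lake))
}

#' 15-day running mean of daily bloom frequency
#'
#' Centered moving average over a 15-calendar-day window. Only days carrying
#' a valid observation participate: unobserved (fully clouded or iced) days
#' are excluded from the averaging set, not zero-filled, and the window is
#' truncated at the series edges.
#'
#' @param dates `Date` vector of observed days (need not be consecutive).
#' @param values frequencies for those days.
#' @param half_window days on each side of the center (default 7, i.e. a
#'   15-day window).
#' @return numeric vector of smoothed values aligned with `dates`.
#' @export
smooth_daily <- function(dates, values, half_window = 7L) {
  n <- length(dates)
  if (n == 0) return(numeric(0))
  ord <- order(dates)
  d <- as.integer(as.Date(dates))[ord]
  v <- values[ord]
  out <- numeric(n)
  for (i in seq_len(n)) {
    sel <- abs(d - d[i]) <= half_window
    out[i] <- mean(v[sel])
  }
  out[order(ord)] <- out
  out
}

#' Bloom-year observation window for a lake and calendar year
#'
#' Northern-Hemisphere lakes and frozen Southern-Hemisphere lakes use the
#' ice-free span of the calendar year (melt..freeze day-of-year when an ice
#' season is present, otherwise Jan 1..Dec 31). Non-frozen Southern lakes
#' use a July--June window shifted six months so that the austral bloom
#' season is not split at Jan 1; the window is labeled with the starting
#' calendar year.
#'
#' @param geometry a `lake_geometry`.
#' @param calendar_year integer year label.
#' @return list with `start`, `end` (Dates), `anchor` (Date the
#'   window-relative day-of-year counts from) and `bloom_year`.
#' @export
bloom_year_window <- function(geometry, calendar_year) {
  y <- as.integer(calendar_year)
  jan1 <- as.Date(sprintf("%d-01-01", y))
  if (geometry$hemisphere == "S" && !isTRUE(geometry$frozen)) {
    start <- as.Date(sprintf("%d-07-01", y))
    list(start = start, end = as.Date(sprintf("%d-06-30", y + 1L)),
         anchor = start, bloom_year = y)
  } else if (!is.null(geometry$ice_cover)) {
    melt <- jan1 + (geometry$ice_cover[["melt"]] - 1L)
    freeze <- jan1 + (geometry$ice_cover[["freeze"]] - 1L)
    list(start = melt, end = freeze, anchor = jan1, bloom_year = y)
  } else {
    list(start = jan1, end = as.Date(sprintf("%d-12-31", y)),
         anchor = jan1, bloom_year = y)
  }
}

#' Phenology and annual frequency within one bloom-year window
#'
#' Onset is the first day in the window with detected bloom area, reported
#' as a 1-based day-of-year relative to the window's anchor (calendar
#' day-of-year for Northern/frozen lakes, days since Jul 1 for shifted
#' Southern windows). Persistence is the inclusive span between first and
#' last bloom days, so a single bloom day has persistence 1. The annual
#' frequency is the median of the 15-day-smoothed daily frequencies over the
#' persistence period. All three are absent when the window has no bloom
#' day; the count of observed days is always reported.
#'
#' @param records data.frame with columns `date`, `A_Bloom`, `A_valid`,
#'   `A_Lake` (one row per day; only rows inside the window are used).
#' @param window a [bloom_year_window()].
#' @return list with `bloom_year`, `onset`, `persistence`,
#'   `annual_frequency` (NA when no bloom) and `n_observations`.
#' @export
phenology <- function(records, window) {
  inw <- records$date >= window$start & records$date <= window$end
  rec <- records[inw, , drop = FALSE]
  rec <- rec[order(rec$date), , drop = FALSE]
  obs <- rec[rec$A_valid > 0, , drop = FALSE]
  n_obs <- nrow(obs)
  bloom_days <- obs$date[obs$A_Bloom > 0]
  if (length(bloom_days) == 0) {
    return(list(bloom_year = window$bloom_year, onset = NA_integer_,
                persistence = NA_integer_, annual_frequency = NA_real_,
                n_observations = n_obs))
  }
  first <- min(bloom_days)
  last <- max(bloom_days)
  freq <- daily_frequency(obs$A_Bloom, obs$A_valid, obs$A_Lake)
  sm <- smooth_daily(obs$date, freq)
  span <- obs$date >= first & obs$date <= last
  list(bloom_year = window$bloom_year,
       onset = as.integer(first - window$anchor) + 1L,
       persistence = as.integer(last - first) + 1L,
       annual_frequency = stats::median(sm[span]),
       n_observations = n_obs)
}

#' Annual metrics table for one lake
#'
#' Applies [bloom_year_window()] and [phenology()] to every year of the
#' study period.
#'
#' @param records daily detection records for the lake (date, A_Bloom,
#'   A_valid, A_Lake).
#' @param geometry the lake's `lake_geometry`.
#' @param years length-2 inclusive year range.
#' @return data.frame with one row per bloom year: `lake`, `bloom_year`,
#'   `onset`, `persistence`, `annual_frequency`, `n_observations`.
#' @export
annual_metrics <- function(records, geometry, years) {
  rows <- lapply(seq(years[1], years[2]), function(y) {
    ph <- phenology(records, bloom_year_window(geometry, y))
    data.frame(lake = geometry$lake_id, bloom_year = ph$bloom_year,
               onset = ph$onset, persistence = ph$persistence,
               annual_frequency = ph$annual_frequency,
               n_observations = ph$n_observations)
  })
  do.call(rbind, rows)
}
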