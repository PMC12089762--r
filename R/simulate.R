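# Synthetic world generator: lakes, daily scenes, meteorology, nutrients,
# all with known ground truth so every downstream stage is testable without
# real satellite data.
#
# Reflectance synthesis targets the detector's decision variables (nFAI sign
# and CIE chromaticity region), not physically realistic spectra.

# Reference spectra (dimensionless Rayleigh-corrected reflectance) chosen so
# that water has negative nFAI and non-green chromaticity, blooms have
# strongly positive nFAI and green chromaticity, clouds are bright white.
.WATER_SPECTRUM <- c(`443` = 0.030, `555` = 0.025, `645` = 0.020,
                     `859` = 0.008, `1240` = 0.010)
.BLOOM_SPECTRUM <- c(`443` = 0.020, `555` = 0.120, `645` = 0.040,
                     `859` = 0.150, `1240` = 0.030)
.CLOUD_SPECTRUM <- c(`443` = 0.30, `555` = 0.30, `645` = 0.30,
                     `859` = 0.30, `1240` = 0.30)
.BANDS <- c(443L, 555L, 645L, 859L, 1240L)

#' Per-lake static attributes drawn from the lake's own random stream
#'
#' @param config a [simulation_config()].
#' @param lake_index 1-based lake index.
#' @return list with `hemisphere`, `frozen`, `ice_cover`, `year_trend`,
#'   `driver` (the factor that truly generates blooms: "temperature" when the
#'   logistic model has a nonzero temperature coefficient, otherwise "none").
#' @export
lake_params <- function(config, lake_index) {
  if (lake_index < 1 || lake_index > config$n_lakes) {
    stop_config("'lake_index' must be in 1..n_lakes")
  }
  set.seed(derive_seed(config$seed, lake_index, 0L))
  hemisphere <- if (stats::runif(1) < config$sh_fraction) "S" else "N"
  frozen <- hemisphere == "N" && stats::runif(1) < config$ice_fraction
  trend <- config$bloom_model$year_trend
  year_trend <- if (length(trend) >= lake_index) trend[[lake_index]] else trend[[1]]
  driver <- if (config$bloom_model$temp_coef != 0) "temperature" else "none"
  list(hemisphere = hemisphere, frozen = frozen,
       ice_cover = if (frozen) c(freeze = config$freeze_doy, melt = config$melt_doy) else NULL,
       year_trend = year_trend, driver = driver)
}

#' Generate the static geometry of one synthetic lake
#'
#' The raster is an equal-area grid fully covered by open water. Historical
#' water-presence probability is high (0.95) over open water and low (0.3)
#' over an outer shoreline strip of `fringe_width` pixels, emulating
#' floating-leaved vegetation zones that the detector must exclude.
#'
#' @inheritParams lake_params
#' @return an object of class `lake_geometry` with fields `lake_mask`,
#'   `area_km2`, `pixel_area_km2`, `water_presence`, `hemisphere`,
#'   `ice_cover` (freeze/melt day-of-year or `NULL`), `frozen`, `include`,
#'   `lake_id` and `lake_index`.
#' @export
generate_lake_geometry <- function(config, lake_index) {
  g <- config$grid_size
  if (g * g < 25) stop_config("grid too small: lake mask would have < 25 pixels")
  par <- lake_params(config, lake_index)
  mask <- matrix(TRUE, g, g)
  row <- matrix(seq_len(g), g, g)
  col <- matrix(seq_len(g), g, g, byrow = TRUE)
  edge_dist <- pmin(row - 1L, g - row, col - 1L, g - col)
  wp <- matrix(0.95, g, g)
  wp[edge_dist < config$fringe_width] <- 0.3
  structure(list(
    lake_mask = mask,
    area_km2 = sum(mask) * config$pixel_area_km2,
    pixel_area_km2 = config$pixel_area_km2,
    water_presence = wp,
    edge_dist = edge_dist,
    hemisphere = par$hemisphere,
    ice_cover = par$ice_cover,
    frozen = par$frozen,
    include = TRUE,
    year_trend = par$year_trend,
    driver = par$driver,
    lake_id = sprintf("lake%03d", lake_index),
    lake_index = as.integer(lake_index)
  ), class = "lake_geometry")
}

#' Generate a daily meteorological series for one lake
#'
#' Air temperature follows a sinusoidal seasonal cycle (phase-shifted six
#' months for Southern-Hemisphere lakes) plus an optional linear warming
#' trend and Gaussian noise; wind speed and precipitation are independent
#' positive-valued noise series (gamma wind; intermittent exponential rain).
#'
#' @inheritParams lake_params
#' @return data.frame with columns `date`, `air_temperature` (deg C),
#'   `wind_speed` (m/s), `precipitation` (mm/day).
#' @export
generate_met_series <- function(config, lake_index) {
  par <- lake_params(config, lake_index)
  set.seed(derive_seed(config$seed, lake_index, 2L))
  dates <- seq(as.Date(sprintf("%d-01-01", config$years[1])),
               as.Date(sprintf("%d-12-31", config$years[2])), by = "day")
  doy <- day_of_year(dates)
  yr <- date_year(dates)
  peak <- if (par$hemisphere == "N") 200 else 17   # austral summer peak
  m <- config$met
  temp <- m$base + m$amplitude * cos(2 * pi * (doy - peak) / 365.25) +
    m$warming * (yr - config$years[1]) +
    stats::rnorm(length(dates), sd = m$noise_sd)
  wind <- stats::rgamma(length(dates), shape = 2, rate = 0.5)
  wet <- stats::runif(length(dates)) < 0.3
  precip <- ifelse(wet, stats::rexp(length(dates), rate = 1 / 8), 0)
  data.frame(date = dates, air_temperature = temp,
             wind_speed = wind, precipitation = precip)
}

#' Generate annual nutrient series for one lake
#'
#' Annual N and P fertilizer usage plus the ten anthropogenic nitrogen input
#' categories (fertilizer NH4/NO3 on cropland and pasture, manure applied or
#' deposited on cropland/pasture/rangeland, and NHx/NOy atmospheric
#' deposition), each a smooth trend plus noise, truncated at zero.
#'
#' @inheritParams lake_params
#' @return data.frame with columns `year`, `fertilizer_N`, `fertilizer_P`
#'   and the ten category columns named in [n_input_categories()].
#' @export
generate_nutrient_series <- function(config, lake_index) {
  set.seed(derive_seed(config$seed, lake_index, 3L))
  years <- seq(config$years[1], config$years[2])
  t <- years - config$years[1]
  n <- length(years)
  smooth_series <- function(base, growth, cv = 0.03) {
    pmax(0, base * (1 + growth * t) + stats::rnorm(n, sd = base * cv))
  }
  cat_base <- c(40, 30, 10, 8, 25, 15, 12, 6, 9, 7)
  cats <- vapply(seq_along(cat_base), function(i) {
    smooth_series(cat_base[i], stats::runif(1, 0, 0.02))
  }, numeric(n))
  colnames(cats) <- n_input_categories()
  out <- data.frame(
    year = years,
    fertilizer_N = smooth_series(120, 0.015),
    fertilizer_P = smooth_series(35, 0.01)
  )
  cbind(out, as.data.frame(cats))
}

#' Canonical names of the ten anthropogenic N input categories
#' @return character vector of length 10.
#' @export
n_input_categories <- function() {
  c("nh4_fert_cropland", "no3_fert_cropland", "nh4_fert_pasture",
    "no3_fert_pasture", "manure_applied_cropland", "manure_applied_pasture",
    "manure_deposited_pasture", "manure_deposited_rangeland",
    "nhx_deposition", "noy_deposition")
}

#' Construct a Scene
#'
#' @param date a `Date`.
#' @param reflectance named list of numeric matrices, one per band, names the
#'   band centers in nm ("443", "555", "645", "859", "1240").
#' @param valid_mask logical matrix, `TRUE` where the pixel was observed
#'   (cloud- and ice-free).
#' @return object of class `scene`.
#' @export
new_scene <- function(date, reflectance, valid_mask) {
  structure(list(date = as.Date(date), reflectance = reflectance,
                 valid_mask = valid_mask), class = "scene")
}

# Is `date` inside the lake's ice-covered season?
in_ice_season <- function(geometry, date) {
  if (!isTRUE(geometry$frozen) || is.null(geometry$ice_cover)) return(FALSE)
  doy <- day_of_year(date)
  freeze <- geometry$ice_cover[["freeze"]]
  melt <- geometry$ice_cover[["melt"]]
  doy >= freeze | doy < melt
}

# Window-relative day-of-year: days since the bloom-year anchor (Jan 1 for
# Northern-Hemisphere and frozen lakes, Jul 1 for non-frozen Southern ones).
window_doy <- function(geometry, date) {
  if (geometry$hemisphere == "S" && !isTRUE(geometry$frozen)) {
    yr <- date_year(date)
    anchor <- as.Date(sprintf("%d-07-01", ifelse(date < as.Date(sprintf("%d-07-01", yr)),
                                                 yr - 1L, yr)))
    as.integer(date - anchor) + 1L
  } else {
    day_of_year(date)
  }
}

# One day's scene plus ground truth, drawn from the ambient RNG stream.
# Used by both generate_scene_series() and the streaming pipeline so that a
# fixed per-lake seed yields identical results in either path.
generate_scene_day <- function(geometry, config, date, temperature) {
  g <- nrow(geometry$lake_mask)
  npix <- g * g
  iced <- in_ice_season(geometry, date)

  cloud <- stats::runif(npix) < config$cloud_prob
  u_bloom <- stats::runif(1)
  bm <- config$bloom_model
  if (iced) {
    p <- 0
  } else if (!is.null(bm$season)) {
    wd <- window_doy(geometry, date)
    p <- if (wd >= bm$season[1] && wd <= bm$season[2]) bm$season_prob else 0
  } else {
    yr <- date_year(date)
    p <- stats::plogis(bm$intercept + bm$temp_coef * temperature +
                         geometry$year_trend * (yr - config$years[1]))
  }
  bloom_day <- u_bloom < p

  truth <- matrix(FALSE, g, g)
  if (bloom_day) {
    interior <- which(geometry$edge_dist >= config$fringe_width)
    ring <- which(geometry$edge_dist >= config$fringe_width &
                    geometry$edge_dist < config$fringe_width + 2L)
    anchor <- ring[ceiling(stats::runif(1) * length(ring))]
    ar <- (anchor - 1L) %% g + 1L
    ac <- (anchor - 1L) %/% g + 1L
    rows <- (seq_len(npix) - 1L) %% g + 1L
    cols <- (seq_len(npix) - 1L) %/% g + 1L
    near <- pmax(abs(rows - ar), abs(cols - ac)) <= config$patch_radius
    patch <- intersect(which(near), interior)
    truth[patch] <- TRUE
  }

  refl <- matrix(rep(.WATER_SPECTRUM, each = npix), npix, 5)
  if (bloom_day) {
    refl[truth, ] <- rep(.BLOOM_SPECTRUM, each = sum(truth))
  }
  if (config$reflectance_noise_sd > 0) {
    refl <- refl + stats::rnorm(npix * 5, sd = config$reflectance_noise_sd)
  }
  refl[cloud, ] <- rep(.CLOUD_SPECTRUM, each = sum(cloud))

  valid <- !cloud & !iced
  reflectance <- lapply(seq_len(5), function(b) matrix(refl[, b], g, g))
  names(reflectance) <- as.character(.BANDS)
  list(scene = new_scene(date, reflectance, matrix(valid, g, g)),
       truth = truth, bloom_day = bloom_day && !iced)
}

#' Generate a daily scene series with ground truth for one lake
#'
#' Bloom occurrence follows a logistic model in air temperature plus the
#' lake's linear year trend (or a designed deterministic season when
#' `bloom_model$season` is set). Bloom pixels receive reflectance with
#' positive nFAI and green chromaticity; clouds censor pixels at random and
#' look white; ice seasons invalidate whole scenes.
#'
#' @param geometry a `lake_geometry` from [generate_lake_geometry()].
#' @param met data.frame from [generate_met_series()] covering every
#'   requested day.
#' @param config the [simulation_config()].
#' @param dates optional `Date` vector (default: every day of `met`).
#' @return list with `scenes` (list of `scene`), `truth` (list of logical
#'   ground-truth bloom masks, recorded even under cloud), and `summary`
#'   data.frame (`date`, `bloom_day`, `n_bloom_pixels`, `n_valid_pixels`).
#' @export
generate_scene_series <- function(geometry, met, config, dates = NULL) {
  if (is.null(dates)) dates <- met$date
  missing <- !(as.integer(dates) %in% as.integer(met$date))
  if (any(missing)) {
    stop_format("met series does not cover ", sum(missing), " requested day(s)")
  }
  temp <- met$air_temperature[match(as.integer(dates), as.integer(met$date))]
  set.seed(derive_seed(config$seed, geometry$lake_index, 4L))
  scenes <- vector("list", length(dates))
  truth <- vector("list", length(dates))
  bloom_day <- logical(length(dates))
  nb <- integer(length(dates))
  nv <- integer(length(dates))
  for (i in seq_along(dates)) {
    d <- generate_scene_day(geometry, config, dates[i], temp[i])
    scenes[[i]] <- d$scene
    truth[[i]] <- d$truth
    bloom_day[i] <- d$bloom_day
    nb[i] <- sum(d$truth)
    nv[i] <- sum(d$scene$valid_mask)
  }
  list(scenes = scenes, truth = truth,
       summary = data.frame(date = dates, bloom_day = bloom_day,
                            n_bloom_pixels = nb, n_valid_pixels = nv))
}
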