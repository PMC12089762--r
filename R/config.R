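#' Simulation configuration
#'
#' Describes a synthetic world of lakes: how many, over which years, raster
#' size, the logistic bloom-occurrence model, cloud censoring, ice seasons and
#' hemisphere mix. The defaults are the package's stated reference world
#' (20 lakes, 2003--2022, 16x16 grids, MODIS-like 500 m pixels).
#'
#' @param n_lakes number of lakes to simulate.
#' @param years length-2 inclusive calendar-year range.
#' @param grid_size pixels per raster side (>= 8 so the lake mask has >= 25
#'   pixels).
#' @param bloom_model list with elements `intercept` (baseline logit),
#'   `temp_coef` (logit units per degree C), `year_trend` (logit units per
#'   year; scalar or one value per lake), and optionally `season`
#'   (length-2 window-relative day-of-year span for a deterministic designed
#'   bloom season) and `season_prob` (daily bloom probability inside that
#'   season, default 1).
#' @param cloud_prob per-day per-pixel probability that a pixel is
#'   cloud-censored, in \[0, 1\].
#' @param ice_fraction fraction of Northern-Hemisphere lakes given a winter
#'   ice season.
#' @param freeze_doy,melt_doy day-of-year of freeze-up and ice melt for iced
#'   lakes.
#' @param sh_fraction fraction of lakes placed in the Southern Hemisphere.
#' @param fringe_width width in pixels of the low water-presence shoreline
#'   strip (emulates floating-leaved vegetation zones).
#' @param pixel_area_km2 area of one pixel.
#' @param patch_radius bloom patch radius in pixels (chebyshev).
#' @param reflectance_noise_sd per-band additive reflectance noise sd.
#' @param met list controlling the meteorological generator: `base` mean air
#'   temperature (deg C), `amplitude` seasonal half-range, `warming` linear
#'   trend (deg C / yr), `noise_sd` daily noise sd.
#' @param seed master integer seed; every stream derives from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_lakes = 20,
                              years = c(2003, 2022),
                              grid_size = 16,
                              bloom_model = list(intercept = -7, temp_coef = 0.3,
                                                 year_trend = 0),
                              cloud_prob = 0.2,
                              ice_fraction = 0.25,
                              freeze_doy = 330,
                              melt_doy = 110,
                              sh_fraction = 0.25,
                              fringe_width = 2,
                              pixel_area_km2 = 0.25,
                              patch_radius = 2,
                              reflectance_noise_sd = 0.002,
                              met = list(base = 12, amplitude = 12, warming = 0,
                                         noise_sd = 2),
                              seed = 1L) {
  years <- as.integer(years)
  if (length(years) != 2 || diff(years) < 1) {
    stop_config("'years' must span at least 2 calendar years")
  }
  if (grid_size < 8) stop_config("'grid_size' must be >= 8")
  if (cloud_prob < 0 || cloud_prob > 1) stop_config("'cloud_prob' must be in [0, 1]")
  if (n_lakes < 1) stop_config("'n_lakes' must be >= 1")
  bm <- utils::modifyList(list(intercept = -7, temp_coef = 0.3, year_trend = 0,
                               season = NULL, season_prob = 1), bloom_model)
  met <- utils::modifyList(list(base = 12, amplitude = 12, warming = 0,
                                noise_sd = 2), met)
  structure(list(
    n_lakes = as.integer(n_lakes), years = years, grid_size = as.integer(grid_size),
    bloom_model = bm, cloud_prob = cloud_prob, ice_fraction = ice_fraction,
    freeze_doy = as.integer(freeze_doy), melt_doy = as.integer(melt_doy),
    sh_fraction = sh_fraction, fringe_width = as.integer(fringe_width),
    pixel_area_km2 = pixel_area_km2, patch_radius = as.integer(patch_radius),
    reflectance_noise_sd = reflectance_noise_sd, met = met,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Detection parameters
#'
#' @param nfai_threshold dimensionless nFAI cutoff above which a pixel can be
#'   flagged as bloom.
#' @param green_region chromaticity screen. Either a list of half-plane
#'   constraints `list(x_max=, y_min=, y_gt_x=)` (the default green locus
#'   region x < 0.35, y > 0.35, y > x) or an n x 2 matrix of CIE (x, y)
#'   polygon vertices.
#' @param water_presence_min minimum historical water-presence probability for
#'   a pixel to be classifiable as bloom, in \[0, 1\].
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(nfai_threshold = 0.02,
                             green_region = list(x_max = 0.35, y_min = 0.35,
                                                 y_gt_x = TRUE),
                             water_presence_min = 0.75) {
  if (water_presence_min < 0 || water_presence_min > 1) {
    stop_config("'water_presence_min' must be in [0, 1]")
  }
  if (is.matrix(green_region)) {
    if (ncol(green_region) != 2 || nrow(green_region) < 3) {
      stop_config("polygon 'green_region' must be an n x 2 matrix with n >= 3")
    }
  } else if (!is.list(green_region)) {
    stop_config("'green_region' must be a constraint list or a polygon matrix")
  }
  structure(list(nfai_threshold = nfai_threshold, green_region = green_region,
                 water_presence_min = water_presence_min),
            class = "detection_params")
}

#' Pipeline configuration
#'
#' Bundles the simulation world, detection parameters, trend periods and
#' significance level for [run_pipeline()].
#'
#' @param sim a [simulation_config()].
#' @param params a [detection_params()].
#' @param period_a,period_b length-2 year ranges compared by
#'   [period_comparison()].
#' @param alpha significance level in (0, 1).
#' @param out_dir optional directory for intermediate CSV artifacts; `NULL`
#'   keeps everything in memory.
#' @param write_scenes if `TRUE` also serialize every simulated scene stack
#'   (large; off by default).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            params = detection_params(),
                            period_a = c(2003, 2015),
                            period_b = c(2016, 2022),
                            alpha = 0.05,
                            out_dir = NULL,
                            write_scenes = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_config("'alpha' must be in (0, 1)")
  if (!inherits(sim, "simulation_config")) stop_config("'sim' must be a simulation_config")
  if (!inherits(params, "detection_params")) stop_config("'params' must be a detection_params")
  structure(list(sim = sim, params = params,
                 period_a = as.integer(period_a), period_b = as.integer(period_b),
                 alpha = alpha, out_dir = out_dir, write_scenes = write_scenes),
            class = "pipeline_config")
}
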