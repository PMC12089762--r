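# End-to-end orchestration: simulate -> detect -> metrics -> trends ->
# drivers -> report. Scenes are generated and classified one day at a time
# so a 20-lake x 20-year world stays desk-scale in memory.

#' Simulate and classify every day of one lake
#'
#' Streams through the lake's full daily record: generates each scene from
#' the lake's own random stream and immediately applies [detect_bloom()],
#' keeping only the per-day areas (and ground truth summary). Ice-season
#' days are recorded as zero-valid observations.
#'
#' @param geometry a `lake_geometry`.
#' @param met the lake's meteorological series.
#' @param config the [simulation_config()].
#' @param params a [detection_params()].
#' @return list with `records` (date, A_Bloom, A_valid, A_Lake),
#'   `truth` (date, bloom_day, n_bloom_pixels) and `bloom_temperatures`
#'   (air temperature on days with detected blooms).
#' @export
simulate_lake_records <- function(geometry, met, config,
                                  params = detection_params()) {
  dates <- met$date
  n <- length(dates)
  set.seed(derive_seed(config$seed, geometry$lake_index, 4L))
  A_Bloom <- numeric(n); A_valid <- numeric(n)
  truth_bloom <- logical(n); truth_px <- integer(n)
  for (i in seq_len(n)) {
    day <- generate_scene_day(geometry, config, dates[i], met$air_temperature[i])
    truth_bloom[i] <- day$bloom_day
    truth_px[i] <- sum(day$truth)
    if (!any(day$scene$valid_mask)) next      # iced or fully clouded
    bm <- detect_bloom(day$scene, geometry, params)
    A_Bloom[i] <- bm$A_Bloom
    A_valid[i] <- bm$A_valid
  }
  records <- data.frame(lake = geometry$lake_id, date = dates,
                        A_Bloom = A_Bloom, A_valid = A_valid,
                        A_Lake = geometry$area_km2)
  list(records = records,
       truth = data.frame(date = dates, bloom_day = truth_bloom,
                          n_bloom_pixels = truth_px),
       bloom_temperatures = met$air_temperature[A_Bloom > 0])
}

# Correlation table feeding assign_best_factor(): daily meteorological
# factors plus the annual fertilizer factors. Lakes with too few matched
# days or bloom years get NA rows for the factors that cannot be computed.
lake_driver_table <- function(records, met, annual, nutrients) {
  met_cors <- tryCatch(daily_driver_correlation(records, met),
                       lakebloom_config_error = function(e) {
                         data.frame(factor = c("temperature", "precipitation", "wind"),
                                    r = NA_real_, p_value = NA_real_, n = 0L)
                       })
  nut <- tryCatch(annual_nutrient_correlation(annual, nutrients),
                  lakebloom_config_error = function(e) NULL)
  fert <- data.frame(factor = c("n_fertilizer", "p_fertilizer"),
                     r = NA_real_, p_value = NA_real_, n = 0L)
  if (!is.null(nut)) {
    fn <- nut[nut$quantity == "fertilizer_N", ]
    fp <- nut[nut$quantity == "fertilizer_P", ]
    fert$r <- c(fn$r, fp$r)
    fert$p_value <- c(fn$p_value, fp$p_value)
    fert$n <- c(fn$n, fp$n)
  }
  rbind(met_cors, fert)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes every stage for each lake (geometry, meteorology, nutrients,
#' daily scenes and detection, annual metrics), then the cross-lake stages
#' (eligibility, per-lake trends and classes, global median series and
#' relative rate, period comparison, driver attribution,
#' temperature-threshold statistics) and assembles a machine-readable
#' report. Identical configuration and seed yield a byte-identical report
#' file via [write_report()].
#'
#' @param config a [pipeline_config()].
#' @return list with `report` plus the intermediate tables (`metrics`,
#'   `trends`, `attribution`, `records` summary).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  sim <- config$sim
  params <- config$params
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  all_metrics <- vector("list", sim$n_lakes)
  all_records <- vector("list", sim$n_lakes)
  attribution <- vector("list", sim$n_lakes)
  bloom_temps <- vector("list", sim$n_lakes)
  bloom_affected <- logical(sim$n_lakes)

  for (i in seq_len(sim$n_lakes)) {
    lake_id <- sprintf("lake%03d", i)
    res <- tryCatch({
      geometry <- generate_lake_geometry(sim, i)
      met <- generate_met_series(sim, i)
      nutrients <- generate_nutrient_series(sim, i)
      lk <- simulate_lake_records(geometry, met, sim, params)
      ann <- annual_metrics(lk$records, geometry, sim$years)
      affected <- any(lk$records$A_Bloom > 0)
      attr_row <- if (affected) {
        ba <- assign_best_factor(lake_driver_table(lk$records, met, ann, nutrients),
                                 alpha = config$alpha)
        data.frame(lake = geometry$lake_id, best_factor = ba$best_factor)
      } else NULL
      if (!is.null(out_dir)) {
        write_detections(lk$records,
                         file.path(out_dir, paste0(lake_id, "_detections.csv")))
        if (isTRUE(config$write_scenes)) {
          series <- generate_scene_series(geometry, met, sim)
          write_scene_stack(series$scenes,
                            file.path(out_dir, paste0(lake_id, "_scenes.csv")))
        }
      }
      list(metrics = ann, records = lk$records, affected = affected,
           attribution = attr_row, temps = lk$bloom_temperatures)
    }, error = function(e) {
      if (inherits(e, "lakebloom_stage_error")) stop(e)
      stop_stage("lake-processing", lake_id, conditionMessage(e))
    })
    all_metrics[[i]] <- res$metrics
    all_records[[i]] <- res$records
    bloom_affected[i] <- res$affected
    attribution[[i]] <- res$attribution
    bloom_temps[[i]] <- res$temps
  }

  metrics <- do.call(rbind, all_metrics)
  attribution <- do.call(rbind, attribution)
  temps <- unlist(bloom_temps)

  eligible <- eligible_lakes(metrics)
  trend_tab <- do.call(rbind, lapply(eligible, function(id) {
    m <- metrics[metrics$lake == id, ]
    lake_trend(m$bloom_year, m$annual_frequency, lake = id,
               metric = "frequency", alpha = config$alpha)
  }))
  classes <- c("Sig. Inc.", "Inc.", "Sig. Dec.", "Dec.")
  class_counts <- if (is.null(trend_tab)) {
    stats::setNames(rep(0L, 4), classes)
  } else {
    tab <- table(factor(trend_tab$trend_class, levels = classes))
    stats::setNames(as.integer(tab), classes)
  }

  affected_ids <- sprintf("lake%03d", which(bloom_affected))
  gseries <- global_median_series(metrics[metrics$lake %in% affected_ids,
                                          , drop = FALSE])
  grate <- if (nrow(gseries) >= 3) {
    tryCatch(global_relative_rate(gseries$bloom_year, gseries$median_frequency),
             lakebloom_config_error = function(e) NULL)
  } else NULL
  pc <- period_comparison(metrics, config$period_a, config$period_b,
                          split = TRUE)
  tstats <- temperature_threshold_stats(temps)

  factor_levels <- c("temperature", "precipitation", "wind", "n_fertilizer",
                     "p_fertilizer", "others")
  n_aff <- sum(bloom_affected)
  best_props <- if (n_aff > 0 && !is.null(attribution)) {
    tab <- table(factor(attribution$best_factor, levels = factor_levels))
    as.list(stats::setNames(as.numeric(tab) / n_aff, factor_levels))
  } else {
    as.list(stats::setNames(rep(NA_real_, 6), factor_levels))
  }

  report <- list(
    config = list(n_lakes = sim$n_lakes, years = sim$years,
                  grid_size = sim$grid_size, cloud_prob = sim$cloud_prob,
                  seed = sim$seed, alpha = config$alpha),
    n_bloom_affected = n_aff,
    n_eligible = length(eligible),
    trend_classes = as.list(class_counts),
    global = list(
      years = gseries$bloom_year,
      median_frequency = gseries$median_frequency,
      rate_percent_per_yr = if (is.null(grate)) NA_real_ else grate$rate_percent_per_yr,
      rate_p_value = if (is.null(grate)) NA_real_ else grate$p_value),
    period_comparison = list(
      period_a = config$period_a, period_b = config$period_b,
      median_rate_a = pc$median_a, median_rate_b = pc$median_b,
      t = pc$t, p_value = pc$p_value, n = pc$n),
    best_factor_proportions = best_props,
    temperature_thresholds = tstats,
    metadata = list(
      relative_rate_convention = "OLS slope / long-term mean x 100",
      best_factor_metric = "max |r| among factors with p < alpha",
      persistence_convention = "inclusive of both endpoint days")
  )

  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "annual_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(trend_tab)) {
      utils::write.csv(trend_tab, file.path(out_dir, "lake_trends.csv"),
                       row.names = FALSE)
    }
    if (!is.null(attribution)) {
      utils::write.csv(attribution, file.path(out_dir, "driver_attribution.csv"),
                       row.names = FALSE)
    }
    write_report(report, file.path(out_dir, "report.json"))
  }

  list(report = report, metrics = metrics, trends = trend_tab,
       attribution = attribution, eligible = eligible)
}
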