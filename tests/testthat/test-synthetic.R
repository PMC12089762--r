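# Synthetic-world generator: geometry, meteorology, nutrients, scenes.

test_that("lake geometry is deterministic, connected and fringed", {
  cfg <- simulation_config(n_lakes = 3, years = c(2003, 2005), grid_size = 16,
                           seed = 11)
  g1 <- generate_lake_geometry(cfg, 1)
  g2 <- generate_lake_geometry(cfg, 1)
  expect_identical(g1, g2)
  expect_true(all(g1$lake_mask))
  expect_gte(sum(g1$lake_mask), 25)
  expect_equal(g1$area_km2, 16 * 16 * cfg$pixel_area_km2)

  # fringe pixel count equals a direct enumeration of the perimeter strip
  strip <- 0L
  for (i in 1:16) for (j in 1:16) {
    if (min(i - 1, 16 - i, j - 1, 16 - j) < cfg$fringe_width) strip <- strip + 1L
  }
  expect_equal(sum(g1$water_presence < 0.5), strip)
  expect_true(all(g1$water_presence[g1$water_presence >= 0.5] >= 0.9))

  small <- simulation_config(grid_size = 8, seed = 1)
  small$grid_size <- 4L   # bypass the constructor to hit the geometry guard
  expect_error(generate_lake_geometry(small, 1), class = "lakebloom_config_error")
  expect_error(simulation_config(grid_size = 4), class = "lakebloom_config_error")
})

test_that("meteorology has the right seasonal phase per hemisphere", {
  cfg <- simulation_config(n_lakes = 2, years = c(2003, 2012), sh_fraction = 0,
                           seed = 5)
  met <- generate_met_series(cfg, 1)
  clim <- tapply(met$air_temperature, as.integer(format(met$date, "%j")), mean)
  peak_doy <- as.integer(names(which.max(clim)))
  expect_true(peak_doy >= 150 && peak_doy <= 250)

  cfg_sh <- simulation_config(n_lakes = 2, years = c(2003, 2012),
                              sh_fraction = 1, seed = 5)
  met_sh <- generate_met_series(cfg_sh, 1)
  clim_sh <- tapply(met_sh$air_temperature, as.integer(format(met_sh$date, "%j")),
                    mean)
  peak_sh <- as.integer(names(which.max(clim_sh)))
  expect_true(peak_sh <= 60 || peak_sh >= 330)
  expect_true(all(met$wind_speed >= 0) && all(met$precipitation >= 0))
})

test_that("a warming trend is recovered by regression on annual means", {
  cfg <- simulation_config(n_lakes = 1, years = c(2003, 2022), sh_fraction = 0,
                           met = list(warming = 0.05), seed = 42)
  met <- generate_met_series(cfg, 1)
  ann <- tapply(met$air_temperature, as.integer(format(met$date, "%Y")), mean)
  yrs <- as.integer(names(ann))
  fit <- summary(lm(ann ~ yrs))$coefficients
  expect_lt(abs(fit[2, 1] - 0.05), 2 * fit[2, 2])
})

test_that("nutrient series conserve the ten-category total", {
  cfg <- simulation_config(n_lakes = 2, years = c(2003, 2019), seed = 3)
  nut <- generate_nutrient_series(cfg, 1)
  expect_equal(nrow(nut), 17)
  expect_true(all(as.matrix(nut[, n_input_categories()]) >= 0))
  subs <- n_input_subsets(nut)
  expect_equal(subs$total_n,
               rowSums(as.matrix(nut[, n_input_categories()])))
  expect_true(all(subs$fertilizer_n_input <= subs$total_n + 1e-12))

  unit <- nut
  unit[, n_input_categories()] <- 1
  s1 <- n_input_subsets(unit)
  expect_equal(s1$total_n, rep(10, nrow(unit)))
  expect_equal(s1$fertilizer_n_input, rep(4, nrow(unit)))
  expect_equal(s1$manure_n, rep(4, nrow(unit)))
  expect_equal(s1$atmospheric_n, rep(2, nrow(unit)))
  expect_equal(s1$cropland_n, rep(3, nrow(unit)))
  expect_equal(s1$pasture_n, rep(4, nrow(unit)))
})

test_that("scene series honor the bloom model and cloud censoring", {
  # degenerate model: bloom probability 0 -> no true bloom pixels ever
  cfg0 <- simulation_config(n_lakes = 1, years = c(2003, 2004),
                            bloom_model = list(intercept = -1e9, temp_coef = 0),
                            sh_fraction = 0, ice_fraction = 0, seed = 2)
  g <- generate_lake_geometry(cfg0, 1)
  met <- generate_met_series(cfg0, 1)
  s0 <- generate_scene_series(g, met, cfg0, dates = met$date[1:60])
  expect_true(all(s0$summary$n_bloom_pixels == 0))

  # cloud_prob = 0 -> every scene fully valid
  cfg1 <- simulation_config(n_lakes = 1, years = c(2003, 2004), cloud_prob = 0,
                            sh_fraction = 0, ice_fraction = 0, seed = 2)
  s1 <- generate_scene_series(g, met, cfg1, dates = met$date[1:30])
  expect_true(all(s1$summary$n_valid_pixels == 16 * 16))

  # determinism: same config + seed -> identical scenes and truth
  s2 <- generate_scene_series(g, met, cfg1, dates = met$date[1:30])
  expect_identical(s1, s2)

  # truth bloom pixels always inside the lake mask
  cfgb <- simulation_config(n_lakes = 1, years = c(2003, 2004),
                            bloom_model = list(intercept = 10, temp_coef = 0),
                            sh_fraction = 0, ice_fraction = 0, seed = 9)
  sb <- generate_scene_series(g, met, cfgb, dates = met$date[1:40])
  for (tr in sb$truth) expect_true(all(g$lake_mask[tr]))

  # met not covering the requested days is a hard error
  expect_error(generate_scene_series(g, met[1:10, ], cfg1,
                                     dates = met$date[1:30]),
               class = "lakebloom_format_error")
})

test_that("empirical bloom-day fraction matches the model probability", {
  # constant bloom probability p = 0.3 via intercept = logit(0.3), temp_coef 0
  p <- 0.3
  cfg <- simulation_config(n_lakes = 1, years = c(2003, 2005),
                           bloom_model = list(intercept = qlogis(p), temp_coef = 0),
                           sh_fraction = 0, ice_fraction = 0, seed = 31)
  g <- generate_lake_geometry(cfg, 1)
  met <- generate_met_series(cfg, 1)
  ser <- generate_scene_series(g, met, cfg, dates = met$date[1:1000])
  phat <- mean(ser$summary$bloom_day)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("ice seasons invalidate whole scenes", {
  cfg <- simulation_config(n_lakes = 1, years = c(2003, 2004), sh_fraction = 0,
                           ice_fraction = 1, seed = 8)
  g <- generate_lake_geometry(cfg, 1)
  expect_true(g$frozen)
  met <- generate_met_series(cfg, 1)
  jan <- met$date[1:30]                     # before melt DOY 110
  ser <- generate_scene_series(g, met, cfg, dates = jan)
  expect_true(all(ser$summary$n_valid_pixels == 0))
})
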