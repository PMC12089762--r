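# Pixel classification: nFAI, chromaticity, and the combined bloom mask.

test_that("nFAI follows the linear-baseline formula", {
  # flat spectrum across 645/859/1240 -> FAI = 0 -> nFAI = 0
  s <- flat_scene(c(`443` = 0.02, `555` = 0.02, `645` = 0.03, `859` = 0.03,
                    `1240` = 0.03))
  expect_equal(compute_nfai(s), matrix(0, 8, 8))

  # R859 elevated 0.05 above the 645-1240 baseline: FAI = 0.05,
  # nFAI = 0.05 / (0.01 + 0.02 + 0.07) = 0.5 by direct evaluation
  s2 <- flat_scene(c(`443` = 0.02, `555` = 0.01, `645` = 0.02, `859` = 0.07,
                     `1240` = 0.02))
  expect_equal(compute_nfai(s2), matrix(0.5, 8, 8), tolerance = 1e-12)

  # clear-water spectrum sits below the baseline -> negative nFAI
  expect_true(all(compute_nfai(flat_scene(water_spectrum)) < 0))

  s3 <- flat_scene(water_spectrum)
  s3$reflectance[["1240"]] <- NULL
  expect_error(compute_nfai(s3), "1240", class = "lakebloom_format_error")
})

test_that("chromaticity projects to the expected CIE coordinates", {
  # equal-energy RGB lands on the transform's white point: the row sums of
  # the sRGB/D65 matrix give (x, y) = (0.31273, 0.32902)
  s <- flat_scene(c(`443` = 0.1, `555` = 0.1, `645` = 0.1, `859` = 0.1,
                    `1240` = 0.1))
  ch <- chromaticity(s)
  expect_equal(ch$x[1, 1], 0.31273, tolerance = 1e-4)
  expect_equal(ch$y[1, 1], 0.32902, tolerance = 1e-4)

  # green-dominated signal falls in the default green region
  sg <- flat_scene(c(`443` = 0.01, `555` = 0.20, `645` = 0.01, `859` = 0.1,
                     `1240` = 0.1))
  chg <- chromaticity(sg)
  expect_true(all(in_green_region(chg$x, chg$y,
                                  detection_params()$green_region)))

  # all-zero radiance is unclassifiable and treated as non-green
  s0 <- flat_scene(c(`443` = 0, `555` = 0, `645` = 0, `859` = 0, `1240` = 0))
  ch0 <- chromaticity(s0)
  expect_true(all(ch0$undefined))
  expect_false(any(in_green_region(ch0$x, ch0$y,
                                   detection_params()$green_region)))
})

test_that("polygon green regions agree with the half-plane default", {
  # the default constraints as an explicit polygon (vertices of the region
  # bounded by x < 0.35, y > 0.35, y > x within the chromaticity triangle)
  poly <- rbind(c(0.35, 0.35), c(0.35, 0.65), c(0, 1), c(0, 0.35))
  xs <- c(0.30, 0.34, 0.36, 0.30, 0.10)
  ys <- c(0.50, 0.36, 0.50, 0.20, 0.80)
  hp <- in_green_region(xs, ys, detection_params()$green_region)
  pg <- in_green_region(xs, ys, poly)
  expect_equal(hp, pg)
})

test_that("detect_bloom flags exactly the bloom-spectrum pixels", {
  g <- toy_geometry(8, fringe = 0)
  s <- flat_scene(water_spectrum)
  idx <- cbind(c(3, 3, 4, 4), c(3, 4, 3, 4))
  for (b in names(bloom_spectrum)) s$reflectance[[b]][idx] <- bloom_spectrum[[b]]
  bm <- detect_bloom(s, g, detection_params())
  expect_equal(sum(bm$bloom), 4)
  expect_true(all(bm$bloom[idx]))
  expect_equal(bm$A_Bloom, 4 * 0.25)
  expect_equal(bm$A_valid, 64 * 0.25)

  # all pixels cloud-censored
  s_cloud <- s
  s_cloud$valid_mask[] <- FALSE
  bm0 <- detect_bloom(s_cloud, g, detection_params())
  expect_equal(bm0$A_valid, 0)
  expect_equal(bm0$A_Bloom, 0)

  # bloom spectrum on a low water-presence fringe is excluded
  gf <- toy_geometry(8, fringe = 2)
  sf <- flat_scene(water_spectrum)
  for (b in names(bloom_spectrum)) sf$reflectance[[b]][1, ] <- bloom_spectrum[[b]]
  bmf <- detect_bloom(sf, gf, detection_params())
  expect_equal(sum(bmf$bloom), 0)

  # excluded lakes are refused
  gx <- toy_geometry(8, include = FALSE)
  expect_error(detect_bloom(s, gx, detection_params()),
               class = "lakebloom_config_error")

  # frozen lake inside its ice season is a precondition violation
  gi <- toy_geometry(8, frozen = TRUE, ice = c(freeze = 330, melt = 110))
  si <- flat_scene(water_spectrum, date = as.Date("2010-01-15"))
  expect_error(detect_bloom(si, gi, detection_params()),
               class = "lakebloom_config_error")
})

test_that("raising the nFAI threshold never adds bloom pixels", {
  cfg <- simulation_config(n_lakes = 1, years = c(2003, 2004),
                           bloom_model = list(intercept = 2, temp_coef = 0),
                           sh_fraction = 0, ice_fraction = 0, seed = 21)
  g <- generate_lake_geometry(cfg, 1)
  met <- generate_met_series(cfg, 1)
  ser <- generate_scene_series(g, met, cfg, dates = met$date[1:20])
  thresholds <- c(-0.1, 0, 0.02, 0.1, 0.3)
  for (s in ser$scenes[1:10]) {
    prev <- NULL
    for (th in thresholds) {
      bm <- detect_bloom(s, g, detection_params(nfai_threshold = th))
      if (!is.null(prev)) expect_true(all(bm$bloom <= prev))
      prev <- bm$bloom
    }
  }
})

test_that("detect_bloom matches the brute-force oracle and mask algebra holds", {
  cfg <- simulation_config(n_lakes = 1, years = c(2003, 2004), grid_size = 16,
                           bloom_model = list(intercept = 0, temp_coef = 0.05),
                           cloud_prob = 0.3, sh_fraction = 0, ice_fraction = 0,
                           seed = 77)
  g <- generate_lake_geometry(cfg, 1)
  met <- generate_met_series(cfg, 1)
  ser <- generate_scene_series(g, met, cfg, dates = met$date[1:25])
  params <- detection_params()
  for (s in ser$scenes) {
    bm <- detect_bloom(s, g, params)
    expect_identical(bm$bloom, brute_force_detect(s, g, params))
    valid_area <- sum(s$valid_mask & g$lake_mask) * g$pixel_area_km2
    nonbloom_valid <- sum(s$valid_mask & g$lake_mask & !bm$bloom) *
      g$pixel_area_km2
    expect_identical(bm$A_Bloom + nonbloom_valid, bm$A_valid)
    expect_identical(bm$A_valid, valid_area)
    expect_true(bm$A_Bloom <= bm$A_valid && bm$A_valid <= bm$A_Lake)
  }
})
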