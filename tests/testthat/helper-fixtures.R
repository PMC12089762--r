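# Shared fixtures: hand-built scenes with known spectra and an independent
# brute-force reference detector used as the oracle for detect_bloom().

# A scene where every pixel carries the same 5-band spectrum.
flat_scene <- function(spectrum, n = 8, date = as.Date("2010-06-15"),
                       valid = TRUE) {
  refl <- lapply(spectrum, function(v) matrix(v, n, n))
  names(refl) <- names(spectrum)
  new_scene(date, refl, matrix(valid, n, n))
}

water_spectrum <- c(`443` = 0.030, `555` = 0.025, `645` = 0.020,
                    `859` = 0.008, `1240` = 0.010)
bloom_spectrum <- c(`443` = 0.020, `555` = 0.120, `645` = 0.040,
                    `859` = 0.150, `1240` = 0.030)

# Minimal all-water geometry matching the generator's conventions.
toy_geometry <- function(n = 8, fringe = 0, hemisphere = "N", frozen = FALSE,
                         ice = NULL, pixel_area = 0.25, include = TRUE) {
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- pmin(row - 1L, n - row, col - 1L, n - col)
  wp <- matrix(0.95, n, n)
  if (fringe > 0) wp[d < fringe] <- 0.3
  structure(list(lake_mask = matrix(TRUE, n, n), area_km2 = n * n * pixel_area,
                 pixel_area_km2 = pixel_area, water_presence = wp,
                 edge_dist = d, hemisphere = hemisphere,
                 ice_cover = ice, frozen = frozen, include = include,
                 year_trend = 0, driver = "none", lake_id = "toy",
                 lake_index = 1L), class = "lake_geometry")
}

# Independent per-pixel reference implementation of the three masking
# conditions, written as plain scalar arithmetic (no shared code with
# detect_bloom beyond the scene container).
brute_force_detect <- function(scene, geometry, params) {
  n <- nrow(geometry$lake_mask)
  srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!scene$valid_mask[i, j] || !geometry$lake_mask[i, j]) next
      if (geometry$water_presence[i, j] < params$water_presence_min) next
      r555 <- scene$reflectance[["555"]][i, j]
      r645 <- scene$reflectance[["645"]][i, j]
      r859 <- scene$reflectance[["859"]][i, j]
      r1240 <- scene$reflectance[["1240"]][i, j]
      r443 <- scene$reflectance[["443"]][i, j]
      fai <- r859 - (r645 + (r1240 - r645) * (859 - 645) / (1240 - 645))
      nfai <- fai / (r555 + r645 + r859)
      if (!is.finite(nfai) || nfai <= params$nfai_threshold) next
      xyz <- srgb2xyz %*% c(r645, r555, r443)
      s <- sum(xyz)
      if (!is.finite(s) || s <= 0) next
      cx <- xyz[1] / s; cy <- xyz[2] / s
      if (cx < params$green_region$x_max && cy > params$green_region$y_min &&
          cy > cx) {
        out[i, j] <- TRUE
      }
    }
  }
  out
}

# Daily records for an unfrozen Northern lake with blooms on given
# calendar days-of-year of one year; full valid coverage unless stated.
records_with_blooms <- function(year = 2010, bloom_doys = integer(0),
                                A_Lake = 100, A_valid = A_Lake,
                                A_Bloom_on = 10) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  ab <- ifelse(as.integer(format(dates, "%j")) %in% bloom_doys, A_Bloom_on, 0)
  data.frame(date = dates, A_Bloom = ab, A_valid = A_valid, A_Lake = A_Lake)
}
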