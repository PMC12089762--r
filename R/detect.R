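# Per-pixel bloom classification: nFAI threshold + CIE chromaticity green
# screen + historical water-presence exclusion.

# sRGB -> XYZ (D65) linear transform, applied to (R645, R555, R443) as (R,G,B).
.RGB_TO_XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                        0.2126729, 0.7151522, 0.0721750,
                        0.0193339, 0.1191920, 0.9503041),
                      nrow = 3, byrow = TRUE)

scene_band <- function(scene, band) {
  b <- scene$reflectance[[as.character(band)]]
  if (is.null(b)) stop_format("scene is missing the ", band, " nm band")
  b
}

#' Normalized floating algae index (nFAI)
#'
#' FAI is the 859 nm reflectance excess over the linear baseline between the
#' 645 and 1240 nm bands:
#' `FAI = R859 - [R645 + (R1240 - R645) * (859 - 645) / (1240 - 645)]`.
#' It is normalized by overall visible/NIR brightness,
#' `nFAI = FAI / (R555 + R645 + R859)`, which preserves the sign of FAI for
#' physically positive reflectances.
#'
#' @param scene a `scene` with bands 555, 645, 859 and 1240 nm.
#' @return numeric matrix of per-pixel nFAI values (NaN where the
#'   normalization denominator is zero).
#' @export
compute_nfai <- function(scene) {
  r555 <- scene_band(scene, 555)
  r645 <- scene_band(scene, 645)
  r859 <- scene_band(scene, 859)
  r1240 <- scene_band(scene, 1240)
  fai <- r859 - (r645 + (r1240 - r645) * (859 - 645) / (1240 - 645))
  fai / (r555 + r645 + r859)
}

#' CIE chromaticity coordinates of each pixel
#'
#' Treats the 645, 555 and 443 nm bands as (R, G, B), maps them to CIE XYZ
#' tristimulus values with the standard sRGB/D65 linear matrix, and projects
#' to chromaticity `x = X/(X+Y+Z)`, `y = Y/(X+Y+Z)`. Pixels with
#' `X+Y+Z <= 0` cannot be classified and are flagged; the detector treats
#' them as non-green.
#'
#' @param scene a `scene` with bands 443, 555 and 645 nm.
#' @return list of matrices `x`, `y` (NA where undefined) and logical
#'   `undefined`.
#' @export
chromaticity <- function(scene) {
  r <- scene_band(scene, 645)
  g <- scene_band(scene, 555)
  b <- scene_band(scene, 443)
  m <- .RGB_TO_XYZ
  X <- m[1, 1] * r + m[1, 2] * g + m[1, 3] * b
  Y <- m[2, 1] * r + m[2, 2] * g + m[2, 3] * b
  Z <- m[3, 1] * r + m[3, 2] * g + m[3, 3] * b
  s <- X + Y + Z
  undefined <- !is.finite(s) | s <= 0
  x <- X / s
  y <- Y / s
  x[undefined] <- NA_real_
  y[undefined] <- NA_real_
  list(x = x, y = y, undefined = undefined)
}

#' Is a chromaticity point inside the configured green region?
#'
#' @param x,y chromaticity coordinates (vectors or matrices).
#' @param region constraint list or polygon matrix, see [detection_params()].
#' @return logical of the same shape; `NA` coordinates are `FALSE`.
#' @export
in_green_region <- function(x, y, region) {
  if (is.matrix(region)) {
    res <- point_in_polygon(as.vector(x), as.vector(y), region)
  } else {
    res <- rep(TRUE, length(x))
    if (!is.null(region$x_max)) res <- res & as.vector(x) < region$x_max
    if (!is.null(region$y_min)) res <- res & as.vector(y) > region$y_min
    if (isTRUE(region$y_gt_x)) res <- res & as.vector(y) > as.vector(x)
  }
  res[is.na(res)] <- FALSE
  if (is.matrix(x)) res <- matrix(res, nrow(x), ncol(x))
  res
}

# Even-odd ray casting; vertices as an n x 2 matrix. Points on an edge may
# fall on either side (ties are measure-zero for the screening use here).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside[is.na(px) | is.na(py)] <- NA
  inside
}

#' Detect bloom pixels in one scene
#'
#' A pixel is flagged as bloom when it is (i) a valid in-lake observation,
#' (ii) above the nFAI threshold, (iii) inside the chromaticity green region,
#' and (iv) over historically persistent open water
#' (`water_presence >= water_presence_min`, excluding floating-leaved
#' vegetation fringes). Areas are pixel counts times the lake's pixel area.
#'
#' @param scene a `scene`.
#' @param geometry a `lake_geometry`. Lakes with `include = FALSE`
#'   (e.g. endorheic lakes whose mineral-rich water mimics green
#'   chromaticity) are refused.
#' @param params a [detection_params()].
#' @return object of class `bloom_mask`: fields `bloom` (logical matrix),
#'   `A_Bloom`, `A_valid`, `A_Lake` (km2) and `date`.
#' @export
detect_bloom <- function(scene, geometry, params = detection_params()) {
  if (!isTRUE(geometry$include)) {
    stop_config("lake '", geometry$lake_id, "' is excluded from analysis")
  }
  if (isTRUE(geometry$frozen) && in_ice_season(geometry, scene$date)) {
    stop_config("scene date ", format(scene$date), " falls inside the ice season")
  }
  valid <- scene$valid_mask & geometry$lake_mask
  if (!any(valid)) {
    empty <- matrix(FALSE, nrow(geometry$lake_mask), ncol(geometry$lake_mask))
    return(structure(list(bloom = empty, A_Bloom = 0, A_valid = 0,
                          A_Lake = geometry$area_km2, date = scene$date),
                     class = "bloom_mask"))
  }
  nfai <- compute_nfai(scene)
  chrom <- chromaticity(scene)
  green <- in_green_region(chrom$x, chrom$y, params$green_region)
  bloom <- valid &
    (nfai > params$nfai_threshold) & !is.na(nfai) &
    green &
    (geometry$water_presence >= params$water_presence_min)
  bloom[is.na(bloom)] <- FALSE
  px <- geometry$pixel_area_km2
  structure(list(bloom = bloom,
                 A_Bloom = sum(bloom) * px,
                 A_valid = sum(valid) * px,
                 A_Lake = geometry$area_km2,
                 date = scene$date),
            class = "bloom_mask")
}
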