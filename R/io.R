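# Readers/writers for the pipeline's on-disk artifacts. All formats are
# plain text: scene stacks as a self-describing long-format CSV with a JSON
# header line (dimensions day x band x y x x, band coordinates in nm, byte
# validity mask), tables as ISO-8601 CSV, geometry and reports as JSON.
# Reflectance is serialized with %.17g so a write/read round trip is
# value-identical.

.SCENE_MAGIC <- "#lakebloom-scene-stack v1"

#' Write a scene stack to a self-describing text file
#'
#' @param scenes list of `scene` objects (one lake, multiple days).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_stack <- function(scenes, path) {
  if (length(scenes) == 0) stop_format("cannot write an empty scene stack")
  dims <- dim(scenes[[1]]$reflectance[[1]])
  bands <- as.integer(names(scenes[[1]]$reflectance))
  dates <- vapply(scenes, function(s) format(s$date), character(1))
  header <- jsonlite::toJSON(list(ny = dims[1], nx = dims[2],
                                  bands_nm = bands, dates = dates),
                             auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.SCENE_MAGIC, paste0("#header ", header),
               "date,band,y,x,value"), con)
  ny <- dims[1]; nx <- dims[2]
  yy <- rep(seq_len(ny), nx)
  xx <- rep(seq_len(nx), each = ny)
  for (s in scenes) {
    d <- format(s$date)
    for (b in names(s$reflectance)) {
      writeLines(paste(d, b, yy, xx,
                       format_full(as.vector(s$reflectance[[b]])), sep = ","), con)
    }
    writeLines(paste(d, "valid", yy, xx,
                     as.integer(as.vector(s$valid_mask)), sep = ","), con)
  }
  invisible(path)
}

#' Read a scene stack written by [write_scene_stack()]
#'
#' Scenes are returned in date order (a shuffled day coordinate is sorted
#' with a warning). All five detection bands and the validity mask must be
#' present.
#'
#' @param path file path.
#' @return list of `scene` objects.
#' @export
read_scene_stack <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || lines[1] != .SCENE_MAGIC) {
    stop_format("not a lakebloom scene stack: ", path)
  }
  header <- jsonlite::fromJSON(sub("^#header ", "", lines[2]))
  required <- c(443L, 555L, 645L, 859L, 1240L)
  missing <- setdiff(required, as.integer(header$bands_nm))
  if (length(missing)) {
    stop_format("scene stack is missing band(s): ",
                paste(missing, collapse = ", "), " nm")
  }
  df <- utils::read.csv(path, skip = 2, colClasses = c("character", "character",
                                                       "integer", "integer",
                                                       "numeric"))
  if (!all(c("date", "band", "y", "x", "value") %in% names(df))) {
    stop_format("scene stack is missing the 'value' data columns")
  }
  dates <- header$dates
  if (is.unsorted(as.Date(dates))) {
    warning("scene stack day coordinate is unordered; returning sorted scenes")
    dates <- dates[order(as.Date(dates))]
  }
  ny <- header$ny; nx <- header$nx
  lapply(dates, function(d) {
    sub <- df[df$date == d, , drop = FALSE]
    refl <- lapply(as.character(required), function(b) {
      rows <- sub[sub$band == b, , drop = FALSE]
      m <- matrix(NA_real_, ny, nx)
      m[cbind(rows$y, rows$x)] <- rows$value
      m
    })
    names(refl) <- as.character(required)
    vr <- sub[sub$band == "valid", , drop = FALSE]
    if (nrow(vr) == 0) stop_format("scene stack is missing the validity mask")
    vm <- matrix(FALSE, ny, nx)
    vm[cbind(vr$y, vr$x)] <- vr$value > 0
    new_scene(as.Date(d), refl, vm)
  })
}

#' Write / read daily detection records
#'
#' CSV with columns `lake`, `date` (ISO-8601), `A_Bloom`, `A_valid`,
#' `A_Lake` in km2.
#'
#' @param records data.frame of daily records.
#' @param path file path.
#' @return `path` invisibly (writer); the data.frame with `date` as `Date`
#'   (reader).
#' @export
write_detections <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  need <- c("date", "A_Bloom", "A_valid", "A_Lake")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_format("detection CSV is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  df
}

#' Serialize lake geometry to JSON (and back)
#'
#' @param geometry a `lake_geometry`.
#' @param path file path.
#' @return `path` invisibly (writer); a `lake_geometry` (reader).
#' @export
write_geometry <- function(geometry, path) {
  payload <- geometry
  payload$lake_mask <- unname(apply(geometry$lake_mask, 1, as.integer, simplify = FALSE))
  payload$water_presence <- unname(apply(geometry$water_presence, 1, identity,
                                         simplify = FALSE))
  payload$edge_dist <- unname(apply(geometry$edge_dist, 1, identity,
                                    simplify = FALSE))
  if (!is.null(geometry$ice_cover)) {   # keep names through JSON
    payload$ice_cover <- as.list(geometry$ice_cover)
  }
  json <- jsonlite::toJSON(unclass(payload), auto_unbox = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  p <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
  g <- p
  g$lake_mask <- p$lake_mask == 1            # fromJSON restores the row matrix
  g$water_presence <- p$water_presence
  g$edge_dist <- p$edge_dist
  if (!is.null(p$ice_cover)) {
    g$ice_cover <- c(freeze = p$ice_cover[["freeze"]], melt = p$ice_cover[["melt"]])
  }
  structure(g, class = "lake_geometry")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys mirror [simulation_config()],
#' [detection_params()] and [pipeline_config()]: e.g. `n_lakes`, `years`,
#' `grid_size`, `bloom_model`, `cloud_prob`, `seed`, `detection`
#' (`nfai_threshold`, `water_presence_min`), `period_a`, `period_b`,
#' `alpha`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(readLines(path, warn = FALSE))
  } else {
    yaml::read_yaml(path)
  }
  sim_keys <- intersect(names(raw), names(formals(simulation_config)))
  sim <- do.call(simulation_config, raw[sim_keys])
  det <- raw$detection %||% list()
  params <- do.call(detection_params,
                    det[intersect(names(det), names(formals(detection_params)))])
  pipeline_config(sim = sim, params = params,
                  period_a = raw$period_a %||% c(2003, 2015),
                  period_b = raw$period_b %||% c(2016, 2022),
                  alpha = raw$alpha %||% 0.05,
                  out_dir = raw$out_dir %||% NULL,
                  write_scenes = isTRUE(raw$write_scenes))
}

# Recursively round doubles to 6 significant digits for stable JSON reports.
signif6 <- function(x) {
  if (is.list(x)) return(lapply(x, signif6))
  if (is.double(x)) return(signif(x, 6))
  x
}

#' Write the machine-readable pipeline report
#'
#' JSON with floating-point values at 6 significant digits; identical
#' configuration and seed produce byte-identical files.
#'
#' @param report report list from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(signif6(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", null = "null")
  writeLines(json, path)
  invisible(path)
}
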