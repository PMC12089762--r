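# Internal helpers: classed conditions, date arithmetic, seed splitting.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("lakebloom_config_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("lakebloom_format_error", "error")))
}

stop_stage <- function(stage, lake, ...) {
  stop(errorCondition(
    sprintf("stage '%s' failed for lake '%s': %s", stage, lake, paste0(...)),
    class = c("lakebloom_stage_error", "error")
  ))
}

#' @keywords internal
day_of_year <- function(date) {
  as.integer(format(date, "%j"))
}

date_year <- function(date) {
  as.integer(format(date, "%Y"))
}

#' Split a reproducible per-lake seed from a master seed
#'
#' Each lake owns independent random streams (geometry, meteorology,
#' nutrients, scenes) so lakes can be regenerated in isolation. Streams are
#' derived deterministically from the master seed; results stay within the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param lake_index 1-based lake index.
#' @param stream integer stream offset (one per generator kind).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, lake_index, stream) {
  s <- (as.double(seed) * 1000003 + as.double(lake_index) * 7919 + stream * 104729)
  as.integer(s %% 2147483647)
}

# Deterministic number formatting that survives a write/read round trip.
format_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
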