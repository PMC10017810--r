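# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used for
#' all along-track and colocalization distances in this package.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance in kilometres.
#' @keywords internal
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

# Normalize longitudes to [-180, 180).
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Signed smallest difference between two longitudes, in degrees.
lon_diff <- function(lon1, lon2) {
  ((lon1 - lon2 + 180) %% 360) - 180
}

check_lat <- function(lat, what = "latitude") {
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stop(what, " must lie in [-90, 90]", call. = FALSE)
  invisible(lat)
}

# Scalar positivity check with a helpful message.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a single positive number", call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' must be non-negative and finite", call. = FALSE)
  invisible(x)
}

# Year-month key ("YYYY-MM") and months-since-0000 index for gap logic.
year_month <- function(time) format(as.POSIXct(time, tz = "UTC"), "%Y-%m")

month_index <- function(ym) {
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}
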