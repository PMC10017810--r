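# Independent oracles used against the package implementations.

# Brute-force Haar statistic: explicit window means by subsetting, no
# cumulative sums. Mirrors the definition, not the implementation.
oracle_haar <- function(distance, values, alpha, spacing) {
  w <- max(1, round(alpha / spacing))
  n <- length(values)
  idx <- (w + 1):(n - w + 1)
  s <- vapply(idx, function(i) {
    left <- mean(values[(i - w):(i - 1)])
    right <- mean(values[i:(i + w - 1)])
    (right - left) / (w * spacing)
  }, numeric(1))
  data.frame(distance_km = distance[idx], statistic = s)
}

# Grid-search minimizer of the residual variance of the two-state model
# over c_high candidates.
oracle_fit_variance <- function(temp, ab, threshold, grid) {
  vals <- vapply(grid, function(c) {
    r <- ab - ifelse(temp >= threshold, c, 0)
    mean((r - mean(r))^2)
  }, numeric(1))
  grid[which.min(vals)]
}

oracle_fit_mse <- function(temp, ab, threshold, grid) {
  vals <- vapply(grid, function(c) {
    r <- ab - ifelse(temp >= threshold, c, 0)
    mean(r^2)
  }, numeric(1))
  grid[which.min(vals)]
}

# Brute-force nearest non-missing grid cell on one day: scan every cell.
oracle_nearest <- function(field, day, lat, lon, lat_tol = Inf, km_tol = Inf) {
  di <- match(as.Date(day), field$dates)
  best <- NULL; best_d <- Inf; best_lat <- Inf; best_lon <- Inf
  for (ila in seq_along(field$lat)) for (ilo in seq_along(field$lon)) {
    v <- field$values[di, ila, ilo]
    if (is.na(v)) next
    glat <- field$lat[ila]; glon <- field$lon[ilo]
    if (abs(glat - lat) > lat_tol) next
    dlon <- abs(((glon - lon + 180) %% 360) - 180)
    if (is.finite(lat_tol) && dlon > lat_tol) next
    d <- geosphere::distHaversine(c(lon, lat), c(glon, glat), r = 6371000) / 1000
    if (d > km_tol) next
    if (d < best_d - 1e-12 ||
        (abs(d - best_d) <= 1e-12 &&
         (glat < best_lat || (glat == best_lat && glon < best_lon)))) {
      best <- v; best_d <- d; best_lat <- glat; best_lon <- glon
    }
  }
  best
}

# Uniform synthetic segment builders used across test files.
make_segment <- function(values, spacing = 5) {
  seg <- data.frame(distance_km = (seq_along(values) - 1) * spacing,
                    abundance_cells_per_ml = values)
  attr(seg, "spacing_km") <- spacing
  class(seg) <- c("cruise_track", "data.frame")
  seg
}

# A small 2-day gridded field on a regular grid, optionally with masked cells.
make_field <- function(variable = "sst", lat = seq(-2, 2, by = 1),
                       lon = seq(10, 14, by = 1),
                       dates = as.Date("2017-06-01") + 0:1,
                       fill = function(d, la, lo) 20 + la + lo / 10) {
  vals <- array(NA_real_, c(length(dates), length(lat), length(lon)))
  for (d in seq_along(dates)) for (la in seq_along(lat)) for (lo in seq_along(lon))
    vals[d, la, lo] <- fill(d, lat[la], lon[lo])
  gridded_field(variable, lat, lon, dates, vals)
}
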