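# Colocalization of abundance observations with daily gridded satellite
# fields: surface filtering, nearest-cell matching under tolerance rules,
# and depth attenuation of surface PAR.

#' Daily gridded environmental field
#'
#' In-memory container for a daily satellite product on a regular lat/lon
#' grid (e.g. blended SST or PAR composites). Values are stored as a 3-D
#' array indexed by (day, lat, lon); missing retrievals are `NA`.
#'
#' @param variable name of the physical variable (e.g. `"sst"`, `"par"`).
#' @param lat,lon grid cell centres in decimal degrees, strictly increasing
#'   and regularly spaced. Longitudes are normalized to \[-180, 180).
#' @param dates vector coercible to `Date`, one entry per day slice.
#' @param values numeric array with dim `c(length(dates), length(lat),
#'   length(lon))`; use `NA` for masked cells.
#' @return an object of class `gridded_field`.
#' @seealso [read_gridded_csv()] to build one from a long-format table,
#'   [colocalize_records()] for matching.
#' @export
gridded_field <- function(variable, lat, lon, dates, values) {
  dates <- as.Date(dates)
  lat <- as.numeric(lat); lon <- normalize_lon(as.numeric(lon))
  check_lat(lat, "grid latitude")
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("grid latitudes must be strictly increasing")
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("grid longitudes must be strictly increasing after normalization")
  values <- array(as.numeric(values), dim = c(length(dates), length(lat), length(lon)))
  spacing <- c(
    lat = if (length(lat) > 1) mean(diff(lat)) else NA_real_,
    lon = if (length(lon) > 1) mean(diff(lon)) else NA_real_
  )
  if (any(!is.na(spacing) & spacing <= 0)) stop("grid spacing must be positive")
  structure(
    list(variable = variable, lat = lat, lon = lon, dates = dates,
         values = values, spacing = spacing),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  cat("Gridded field '", x$variable, "': ",
      length(x$lat), " x ", length(x$lon), " grid, ",
      length(x$dates), " day(s) [", format(min(x$dates)), " .. ",
      format(max(x$dates)), "], ",
      sum(is.na(x$values)), " masked cell-days\n", sep = "")
  invisible(x)
}

#' Read a gridded field from a long-format CSV
#'
#' Expects columns `date`, `lat`, `lon`, `value`; one row per cell-day.
#' Cells absent from the table are masked (`NA`).
#'
#' @param path CSV file path.
#' @param variable variable name to record on the field.
#' @return a [gridded_field()].
#' @export
read_gridded_csv <- function(path, variable = "field") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lat", "lon", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gridded CSV is missing column(s): ", paste(miss, collapse = ", "))
  lat <- sort(unique(d$lat)); lon <- sort(unique(normalize_lon(d$lon)))
  dates <- sort(unique(as.Date(d$date)))
  vals <- array(NA_real_, dim = c(length(dates), length(lat), length(lon)))
  it <- match(as.Date(d$date), dates)
  ila <- match(d$lat, lat); ilo <- match(normalize_lon(d$lon), lon)
  vals[cbind(it, ila, ilo)] <- d$value
  gridded_field(variable, lat, lon, dates, vals)
}

#' Write a gridded field as a long-format CSV
#' @param field a [gridded_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gridded_csv <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  idx <- which(!is.na(field$values), arr.ind = TRUE)
  d <- data.frame(
    date = format(field$dates[idx[, 1]]),
    lat = field$lat[idx[, 2]],
    lon = field$lon[idx[, 3]],
    value = field$values[idx]
  )
  utils::write.csv(d[order(d$date, d$lat, d$lon), ], path, row.names = FALSE)
  invisible(path)
}

#' Restrict observations to the surface ocean
#'
#' Keeps records with depth at most `max_depth` metres (inclusive), the
#' surface criterion applied throughout before any model fitting or
#' station averaging.
#'
#' @param observations data frame with a `depth_m` column.
#' @param max_depth maximum depth in metres (default 50).
#' @return the retained rows, order preserved.
#' @export
filter_surface <- function(observations, max_depth = 50) {
  check_positive(max_depth, "max_depth")
  if (!"depth_m" %in% names(observations)) stop("observations need a 'depth_m' column")
  observations[!is.na(observations$depth_m) & observations$depth_m <= max_depth, ,
               drop = FALSE]
}

#' Attenuate surface PAR to depth
#'
#' Exponential light attenuation `par * exp(-k * depth)` with a constant
#' attenuation coefficient, the convention used to bring satellite surface
#' PAR to the sampling depth of each record.
#'
#' @param par_surface surface PAR (any consistent flux unit), non-negative.
#' @param depth depth in metres, non-negative.
#' @param k attenuation coefficient per metre (default 0.1).
#' @return attenuated PAR, same unit as `par_surface`.
#' @examples
#' attenuate_par(50, 10)   # 50 * exp(-1)
#' @export
attenuate_par <- function(par_surface, depth, k = 0.1) {
  check_nonnegative(par_surface, "par_surface")
  check_nonnegative(depth, "depth")
  check_nonnegative(k, "k")
  par_surface * exp(-k * depth)
}

# Nearest non-missing grid cell for one observation on one day slice.
# Candidates are pre-restricted by the caller; ties on great-circle
# distance break by ascending (lat, lon). Returns NA if no candidate.
nearest_cell_value <- function(field, day_idx, lat, lon, cand) {
  if (nrow(cand) == 0) return(NA_real_)
  v <- field$values[cbind(day_idx, cand$ila, cand$ilo)]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  cand <- cand[ok, , drop = FALSE]; v <- v[ok]
  d <- haversine_km(lat, lon, cand$lat, cand$lon)
  ord <- order(d, cand$lat, cand$lon)
  v[ord[1]]
}

#' Match observations to daily gridded temperature and PAR
#'
#' Attaches, to each observation, the nearest non-missing same-UTC-day grid
#' value of each field, under the product tolerances: temperature within
#' `temp_tolerance` degrees on each axis of the native grid, PAR within
#' `par_tolerance` km great-circle distance. Records that fail either match
#' (no overlapping day, all candidate cells masked, or outside tolerance)
#' are dropped, mirroring the treatment of days with missing satellite
#' retrievals. Matched PAR is then attenuated to the record's depth with
#' coefficient `k`.
#'
#' Nearness is great-circle distance to the cell centre; exact ties break
#' deterministically by ascending (lat, lon).
#'
#' @param observations data frame with columns `lat`, `lon`, `depth_m`,
#'   `time_iso8601` plus any others (preserved).
#' @param temperature_field,par_field [gridded_field()] objects. Either may
#'   be `NULL` to skip that match.
#' @param temp_tolerance per-axis tolerance in degrees for the temperature
#'   grid (default 0.25).
#' @param par_tolerance great-circle tolerance in km for PAR (default 9).
#' @param k PAR attenuation coefficient per metre (default 0.1).
#' @return the matched rows with `temperature_C` and `par` columns filled;
#'   attribute `"dropped"` holds counts by reason (`no_date`, `no_temp`,
#'   `no_par`).
#' @export
colocalize_records <- function(observations, temperature_field = NULL,
                               par_field = NULL, temp_tolerance = 0.25,
                               par_tolerance = 9, k = 0.1) {
  obs <- observations
  n <- nrow(obs)
  if (is.null(n) || n == 0) {
    out <- observations
    attr(out, "dropped") <- c(no_date = 0L, no_temp = 0L, no_par = 0L)
    return(out)
  }
  check_positive(temp_tolerance, "temp_tolerance")
  check_positive(par_tolerance, "par_tolerance")
  obs$lon <- normalize_lon(obs$lon)
  check_lat(obs$lat, "observation latitude")
  obs_date <- as.Date(as.POSIXct(obs$time_iso8601, tz = "UTC"))

  tvals <- rep(NA_real_, n); pvals <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  # precompute candidate index tables lazily per field
  t_grid <- if (!is.null(temperature_field))
    expand.grid(ila = seq_along(temperature_field$lat),
                ilo = seq_along(temperature_field$lon))
  p_grid <- if (!is.null(par_field))
    expand.grid(ila = seq_along(par_field$lat), ilo = seq_along(par_field$lon))

  for (i in seq_len(n)) {
    ti <- if (!is.null(temperature_field))
      match(obs_date[i], temperature_field$dates) else NA_integer_
    pi <- if (!is.null(par_field)) match(obs_date[i], par_field$dates) else NA_integer_
    if ((!is.null(temperature_field) && is.na(ti)) ||
        (!is.null(par_field) && is.na(pi))) {
      reason[i] <- "no_date"; next
    }
    if (!is.null(temperature_field)) {
      f <- temperature_field
      cand <- t_grid[abs(f$lat[t_grid$ila] - obs$lat[i]) <= temp_tolerance &
                       abs(lon_diff(f$lon[t_grid$ilo], obs$lon[i])) <= temp_tolerance, ,
                     drop = FALSE]
      cand$lat <- f$lat[cand$ila]; cand$lon <- f$lon[cand$ilo]
      tvals[i] <- nearest_cell_value(f, ti, obs$lat[i], obs$lon[i], cand)
      if (is.na(tvals[i])) { reason[i] <- "no_temp"; next }
    }
    if (!is.null(par_field)) {
      f <- par_field
      # coarse degree prefilter before the great-circle cut
      dlat_max <- par_tolerance / 111.195 + 1e-9
      cand <- p_grid[abs(f$lat[p_grid$ila] - obs$lat[i]) <= dlat_max, , drop = FALSE]
      cand$lat <- f$lat[cand$ila]; cand$lon <- f$lon[cand$ilo]
      if (nrow(cand)) {
        within <- haversine_km(obs$lat[i], obs$lon[i], cand$lat, cand$lon) <= par_tolerance
        cand <- cand[within, , drop = FALSE]
      }
      pvals[i] <- nearest_cell_value(f, pi, obs$lat[i], obs$lon[i], cand)
      if (is.na(pvals[i])) { reason[i] <- "no_par"; next }
    }
  }

  keep <- is.na(reason)
  dropped <- c(no_date = sum(reason == "no_date", na.rm = TRUE),
               no_temp = sum(reason == "no_temp", na.rm = TRUE),
               no_par = sum(reason == "no_par", na.rm = TRUE))
  out <- obs[keep, , drop = FALSE]
  if (!is.null(temperature_field)) out$temperature_C <- tvals[keep]
  if (!is.null(par_field))
    out$par <- attenuate_par(pvals[keep], out$depth_m, k = k)
  if (nrow(out) == 0 && n > 0)
    warning("no observations could be colocalized (dropped: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), ")")
  attr(out, "dropped") <- dropped
  out
}

#' Cumulative along-track distance
#'
#' Haversine distance (Earth radius 6371 km) accumulated along an ordered
#' sequence of positions, giving the km coordinate on which wavelet widths
#' and separation rules are expressed.
#'
#' @param lat,lon ordered position vectors in decimal degrees.
#' @return numeric vector of cumulative km, starting at 0.
#' @export
along_track_distance <- function(lat, lon) {
  if (length(lat) != length(lon)) stop("lat and lon must have equal length")
  if (length(lat) < 1) stop("at least one point is required")
  check_lat(lat)
  if (length(lat) == 1) return(0)
  lon <- normalize_lon(lon)
  step <- haversine_km(lat[-length(lat)], lon[-length(lon)], lat[-1], lon[-1])
  c(0, cumsum(step))
}
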