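# Seeded synthetic-data generators emulating the three kinds of input the
# diagnostics run on: a global surface snapshot with a bimodal abundance
# distribution, underway cruise tracks with planted niche transitions, and
# monthly station series with planted delta-correlation structure. Every
# generator returns the data together with its ground truth, so parameter
# recovery is testable end to end.

#' Settings for the global surface generator
#'
#' The surface snapshot is driven by a latitudinal temperature gradient
#' (cosine of latitude scaled to `[0, t_max]` deg C, monotone poleward
#' cooling) with a two-state abundance response: above `threshold`,
#' abundance is `c_high` times mean-preserving lognormal noise of
#' coefficient of variation `noise_cv`; below it, abundance is exactly 0
#' with probability `zero_cluster_fraction` and otherwise a small lognormal
#' background (median `low_median`). Exact zeros are generated on purpose
#' so the zeros-to-log10(1)=0 convention is exercised downstream.
#'
#' @param threshold viability temperature, deg C (default 13).
#' @param c_high viable-state mean abundance, cells/mL (default 42000).
#' @param noise_cv coefficient of variation of viable-state multiplicative
#'   noise (default 0.8, giving roughly a third of a decade of log10
#'   scatter). The noise distribution of real underway abundance data is
#'   not characterized; this lognormal is a stand-in.
#' @param zero_cluster_fraction probability a below-threshold record is
#'   exactly 0 (default 0.8).
#' @param low_median,low_sdlog median (cells/mL) and lognormal sdlog of the
#'   nonzero below-threshold background (defaults 10 and 1).
#' @param t_max equatorial temperature, deg C (default 30).
#' @param par_max equatorial surface PAR (default 60, MODIS-like units of
#'   mol photons m^-2 d^-1); PAR follows the same cosine profile with
#'   additive noise `par_noise_sd` truncated at 0.
#' @param par_noise_sd sd of PAR noise (default 3).
#' @param max_depth sampling depths are uniform on `[0, max_depth]` m
#'   (default 50).
#' @param start_date first possible sampling date (records are spread
#'   uniformly over one year).
#' @return a list of settings for [generate_global_surface()].
#' @export
global_surface_cfg <- function(threshold = 13, c_high = 42000,
                               noise_cv = 0.8, zero_cluster_fraction = 0.8,
                               low_median = 10, low_sdlog = 1,
                               t_max = 30, par_max = 60, par_noise_sd = 3,
                               max_depth = 50, start_date = "2017-01-01") {
  if (noise_cv < 0) stop("noise scale (noise_cv) must be non-negative")
  if (c_high < 0) stop("c_high must be non-negative")
  if (zero_cluster_fraction < 0 || zero_cluster_fraction > 1)
    stop("zero_cluster_fraction must be in [0, 1]")
  as.list(environment())
}

#' Generate a global surface abundance snapshot
#'
#' Draws `n` surface observations (depth at most 50 m) at uniform random
#' latitudes and longitudes, with temperature set by the latitudinal
#' profile and abundance by the two-state response described in
#' [global_surface_cfg()]. The log10-abundance distribution is bimodal: a
#' cluster at/near zero poleward of the thermal boundary and a
#' high-abundance cluster in the warm band — the global structure the
#' two-state model summarizes.
#'
#' @param n number of observations (at least 1).
#' @param seed RNG seed; identical `(cfg, seed)` reproduce bit-identical
#'   output.
#' @param cfg settings from [global_surface_cfg()].
#' @return list with `observations` (data frame: `lat`, `lon`, `depth_m`,
#'   `time_iso8601`, `abundance_cells_per_ml`, `temperature_C`, `par`) and
#'   `truth` (class `synthetic_truth`).
#' @export
generate_global_surface <- function(n, seed = 1, cfg = global_surface_cfg()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  with_seed(seed, {
    lat <- stats::runif(n, -90, 90)
    lon <- stats::runif(n, -180, 180)
    depth <- stats::runif(n, 0, cfg$max_depth)
    time <- as.POSIXct(cfg$start_date, tz = "UTC") +
      stats::runif(n, 0, 364) * 86400
    temp <- cfg$t_max * cos(lat * pi / 180)
    par <- pmax(cfg$par_max * cos(lat * pi / 180) +
                  stats::rnorm(n, 0, cfg$par_noise_sd), 0)
    above <- temp >= cfg$threshold
    ab <- numeric(n)
    if (any(above)) {
      if (cfg$noise_cv > 0) {
        sdlog <- sqrt(log(1 + cfg$noise_cv^2))
        ab[above] <- stats::rlnorm(sum(above),
                                   meanlog = log(cfg$c_high) - sdlog^2 / 2,
                                   sdlog = sdlog)
      } else ab[above] <- cfg$c_high
    }
    if (any(!above)) {
      nb <- sum(!above)
      nonzero <- stats::runif(nb) >= cfg$zero_cluster_fraction
      bg <- numeric(nb)
      if (any(nonzero))
        bg[nonzero] <- stats::rlnorm(sum(nonzero),
                                     meanlog = log(cfg$low_median),
                                     sdlog = cfg$low_sdlog)
      ab[!above] <- bg
    }
    obs <- data.frame(
      lat = lat, lon = lon, depth_m = depth,
      time_iso8601 = format(time, "%Y-%m-%dT%H:%M:%SZ"),
      abundance_cells_per_ml = ab, temperature_C = temp, par = par
    )
    truth <- structure(
      list(kind = "global_surface", true_threshold_T = cfg$threshold,
           true_high_state = cfg$c_high, noise_cv = cfg$noise_cv,
           zero_cluster_fraction = cfg$zero_cluster_fraction, seed = seed),
      class = "synthetic_truth")
    list(observations = obs, truth = truth)
  })
}

#' Settings for the cruise-track generator
#'
#' Tracks are piecewise-constant abundance regimes joined by linear ramps:
#' `length(means)` regimes separated by `boundaries_km`, each ramp of width
#' `transition_width_km` centred on its boundary, plus additive Gaussian
#' noise truncated at zero. Ground-truth transition positions are the ramp
#' midpoints, i.e. `boundaries_km` themselves. The defaults plant one shift
#' of 1.5e5 cells/mL over 30 km — the magnitude of the sustained shifts
#' underway flow-cytometry transects record ("order 1e5 cells/mL in under
#' 150 km").
#'
#' @param length_km track length (default 2000).
#' @param spacing_km sample spacing (default 5, roughly the native
#'   along-track resolution of underway flow cytometry).
#' @param boundaries_km strictly increasing regime boundaries, inside
#'   `(0, length_km)` (default 1000).
#' @param means regime mean abundances, `length(boundaries_km) + 1` values
#'   (default `c(160000, 10000)`).
#' @param transition_width_km ramp width, must be positive (default 30).
#' @param noise_sd additive abundance noise sd (default 5000).
#' @param temp_means optional regime mean temperatures (deg C); when given,
#'   temperature follows the same ramp geometry with additive noise
#'   `temp_noise_sd`, so abundance regimes coincide with thermal regimes.
#' @param temp_noise_sd sd of temperature noise (default 0.3).
#' @param lat0 track latitude; the track runs eastward along this parallel.
#' @param speed_kmh vessel speed used to assign timestamps (default 20).
#' @param start_date start time of the track.
#' @param cruise_id identifier recorded on every sample.
#' @return a list of settings for [generate_cruise_track()].
#' @export
cruise_track_cfg <- function(length_km = 2000, spacing_km = 5,
                             boundaries_km = 1000,
                             means = c(160000, 10000),
                             transition_width_km = 30, noise_sd = 5000,
                             temp_means = NULL, temp_noise_sd = 0.3,
                             lat0 = 0, speed_kmh = 20,
                             start_date = "2017-06-01",
                             cruise_id = "SYN1") {
  if (transition_width_km <= 0) stop("transition_width_km must be positive")
  if (length(boundaries_km) &&
      (any(diff(boundaries_km) <= 0) ||
       any(boundaries_km <= 0 | boundaries_km >= length_km)))
    stop("regime boundaries must be strictly increasing and inside (0, length_km)")
  if (length(means) != length(boundaries_km) + 1)
    stop("need exactly length(boundaries_km) + 1 regime means")
  if (!is.null(temp_means) && length(temp_means) != length(means))
    stop("temp_means must match the number of regimes")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  as.list(environment())
}

# Piecewise-constant regimes joined by linear ramps of width w centred on
# each boundary.
regime_profile <- function(x, boundaries, means, width) {
  y <- rep(means[1], length(x))
  for (j in seq_along(boundaries)) {
    frac <- pmin(pmax((x - (boundaries[j] - width / 2)) / width, 0), 1)
    y <- y + (means[j + 1] - means[j]) * frac
  }
  y
}

#' Generate a cruise track with planted transitions
#'
#' @param cfg settings from [cruise_track_cfg()].
#' @param seed RNG seed.
#' @return list with `track` (class `cruise_track`: `cruise_id`,
#'   `distance_km`, `lat`, `lon`, `time_iso8601`,
#'   `abundance_cells_per_ml`, optionally `temperature_C`; uniform spacing
#'   recorded in attribute `"spacing_km"`) and `truth` (transition
#'   positions at the ramp midpoints).
#' @export
generate_cruise_track <- function(cfg = cruise_track_cfg(), seed = 1) {
  with_seed(seed, {
    x <- seq(0, cfg$length_km, by = cfg$spacing_km)
    ab <- regime_profile(x, cfg$boundaries_km, cfg$means, cfg$transition_width_km)
    if (cfg$noise_sd > 0)
      ab <- pmax(ab + stats::rnorm(length(x), 0, cfg$noise_sd), 0)
    lon <- normalize_lon(cfg$lat0 * 0 + x / (111.195 * cos(cfg$lat0 * pi / 180)))
    time <- as.POSIXct(cfg$start_date, tz = "UTC") + x / cfg$speed_kmh * 3600
    track <- data.frame(
      cruise_id = cfg$cruise_id, distance_km = x,
      lat = cfg$lat0, lon = lon,
      time_iso8601 = format(time, "%Y-%m-%dT%H:%M:%SZ"),
      abundance_cells_per_ml = ab
    )
    if (!is.null(cfg$temp_means)) {
      tt <- regime_profile(x, cfg$boundaries_km, cfg$temp_means,
                           cfg$transition_width_km)
      if (cfg$temp_noise_sd > 0)
        tt <- tt + stats::rnorm(length(x), 0, cfg$temp_noise_sd)
      track$temperature_C <- tt
    }
    class(track) <- c("cruise_track", "data.frame")
    attr(track, "spacing_km") <- cfg$spacing_km
    truth <- structure(
      list(kind = "cruise_track",
           true_transition_positions = cfg$boundaries_km,
           regime_means = cfg$means,
           transition_width_km = cfg$transition_width_km, seed = seed),
      class = "synthetic_truth")
    list(track = track, truth = truth)
  })
}

#' Settings for the station time-series generator
#'
#' Monthly station series are built by integrating jointly Gaussian
#' consecutive-month deltas `(dT, dPAR, dPro)` with a planted correlation
#' matrix, so the population correlations between deltas equal the planted
#' values exactly (up to sampling error in any finite realization).
#' Optional deterministic seasonal cycles can be added to the temperature
#' and PAR series; note that a nonzero seasonal amplitude perturbs the
#' realized delta-correlations away from the planted values, so the
#' defaults leave them at 0.
#'
#' @param n_months number of months (default 360).
#' @param start first month, `"YYYY-MM"` (default `"1991-01"`).
#' @param cor_t_pro,cor_par_pro,cor_t_par planted Pearson correlations
#'   between monthly deltas; the implied 3x3 matrix must be positive
#'   semi-definite. Defaults (0, -0.35, 0.5) echo the weak
#'   temperature-abundance and negative light-abundance coupling seen in
#'   subtropical station records.
#' @param sd_t,sd_par,sd_pro delta standard deviations (defaults 0.8 deg C,
#'   5 PAR units, 30000 cells/mL).
#' @param base_t,base_par,base_pro series baselines (defaults 25, 40,
#'   150000).
#' @param seasonal_t_amp,seasonal_par_amp amplitudes of an added sinusoidal
#'   annual cycle (defaults 0; see above).
#' @param missing_prob probability each month is missing (default 0).
#' @return a list of settings for [generate_station_series()].
#' @export
station_series_cfg <- function(n_months = 360, start = "1991-01",
                               cor_t_pro = 0, cor_par_pro = -0.35,
                               cor_t_par = 0.5,
                               sd_t = 0.8, sd_par = 5, sd_pro = 30000,
                               base_t = 25, base_par = 40, base_pro = 150000,
                               seasonal_t_amp = 0, seasonal_par_amp = 0,
                               missing_prob = 0) {
  if (any(abs(c(cor_t_pro, cor_par_pro, cor_t_par)) > 1))
    stop("planted correlations must lie in [-1, 1]")
  if (missing_prob < 0 || missing_prob >= 1) stop("missing_prob must be in [0, 1)")
  as.list(environment())
}

#' Generate a monthly station series with planted delta-correlations
#'
#' @param cfg settings from [station_series_cfg()].
#' @param seed RNG seed.
#' @return list with `monthly` (class `station_monthly`: `year_month`,
#'   `temperature_C`, `par`, `abundance_cells_per_ml`, `n_cruises`) and
#'   `truth` carrying the planted correlations. Abundance is an anomaly
#'   series around its baseline and is deliberately not clamped at zero,
#'   which would distort the planted correlations.
#' @export
generate_station_series <- function(cfg = station_series_cfg(), seed = 1) {
  R <- matrix(c(1, cfg$cor_t_par, cfg$cor_t_pro,
                cfg$cor_t_par, 1, cfg$cor_par_pro,
                cfg$cor_t_pro, cfg$cor_par_pro, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("planted correlation matrix is not positive semi-definite")
  # zero out numerically-null eigenvalues so degenerate (singular) planted
  # correlations reproduce their exact linear dependencies
  lam <- ifelse(ev$values < 1e-12, 0, ev$values)
  L <- ev$vectors %*% diag(sqrt(lam))
  sds <- c(cfg$sd_t, cfg$sd_par, cfg$sd_pro)
  with_seed(seed, {
    nd <- cfg$n_months - 1L
    Z <- matrix(stats::rnorm(3 * nd), nrow = 3)
    deltas <- t(L %*% Z) * rep(sds, each = nd)  # columns: dT, dPAR, dPro
    series <- apply(rbind(0, deltas), 2, cumsum)
    m <- seq_len(cfg$n_months) - 1L
    t_series <- cfg$base_t + series[, 1] +
      cfg$seasonal_t_amp * sin(2 * pi * m / 12)
    par_series <- cfg$base_par + series[, 2] +
      cfg$seasonal_par_amp * sin(2 * pi * m / 12)
    pro_series <- cfg$base_pro + series[, 3]
    start_idx <- month_index(cfg$start)
    ym_idx <- start_idx + m
    ym <- sprintf("%04d-%02d", ym_idx %/% 12L, ym_idx %% 12L + 1L)
    keep <- stats::runif(cfg$n_months) >= cfg$missing_prob
    monthly <- data.frame(
      year_month = ym[keep],
      temperature_C = t_series[keep],
      par = par_series[keep],
      abundance_cells_per_ml = pro_series[keep],
      n_cruises = 1L
    )
    class(monthly) <- c("station_monthly", "data.frame")
    truth <- structure(
      list(kind = "station_series",
           true_correlations = c(t_pro = cfg$cor_t_pro,
                                 par_pro = cfg$cor_par_pro,
                                 t_par = cfg$cor_t_par),
           delta_sds = c(t = cfg$sd_t, par = cfg$sd_par, pro = cfg$sd_pro),
           seed = seed),
      class = "synthetic_truth")
    list(monthly = monthly, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (", x$kind, ")\n", sep = "")
  for (nm in setdiff(names(x), "kind"))
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write ground truth as a JSON sidecar
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
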