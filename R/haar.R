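# Along-track machinery: uniform resampling, the Haar sustained-change
# statistic, scalograms, transition detection, and the scale-dependent
# correlation between wavelet-filtered abundance and temperature.

#' Default parameters for Haar transition detection
#'
#' Collects the constants of the along-track analysis: wavelet half-width
#' `alpha` (150 km, where the number of detected peaks stabilizes as the
#' width grows), the low-level filter threshold (10 cells/mL/km), the
#' minimum separation between reported transitions (100 km), the regime
#' crossing threshold (75000 cells/mL, about half of peak Pacific surface
#' abundance), the resampling spacing (5 km) and the maximum raw-data gap
#' interpolated across (100 km).
#'
#' @param alpha wavelet half-width, km.
#' @param filter_threshold minimum `|S|`, cells/mL/km.
#' @param min_separation minimum distance between transitions, km.
#' @param regime_threshold abundance threshold whose crossing is flagged,
#'   cells/mL.
#' @param resample_spacing uniform grid spacing, km.
#' @param max_gap raw gaps larger than this split the track, km.
#' @return a list of class `haar_params`.
#' @export
haar_params <- function(alpha = 150, filter_threshold = 10,
                        min_separation = 100, regime_threshold = 75000,
                        resample_spacing = 5, max_gap = 100) {
  for (nm in c("alpha", "filter_threshold", "min_separation",
               "regime_threshold", "resample_spacing", "max_gap"))
    check_positive(get(nm), nm)
  structure(list(alpha = alpha, filter_threshold = filter_threshold,
                 min_separation = min_separation,
                 regime_threshold = regime_threshold,
                 resample_spacing = resample_spacing, max_gap = max_gap),
            class = "haar_params")
}

# Coerce a track-like data frame: needs distance_km (or lat/lon to derive
# it) and abundance_cells_per_ml.
as_track <- function(track) {
  if (!"distance_km" %in% names(track)) {
    if (!all(c("lat", "lon") %in% names(track)))
      stop("track needs 'distance_km' or 'lat'/'lon' columns")
    track$distance_km <- along_track_distance(track$lat, track$lon)
  }
  if (!"abundance_cells_per_ml" %in% names(track))
    stop("track needs an 'abundance_cells_per_ml' column")
  if (is.unsorted(track$distance_km, strictly = TRUE))
    stop("track distances must be strictly increasing")
  track
}

#' Resample a track onto a uniform grid
#'
#' Linear interpolation of abundance (and temperature, position, time where
#' present) onto a uniform along-track grid. Consecutive raw samples
#' further apart than `max_gap` split the track into independent segments:
#' interpolating across a large gap would fabricate a sustained change, so
#' none is attempted. Each segment's grid starts at its first raw sample;
#' a trailing partial interval shorter than the spacing is dropped to keep
#' the grid uniform.
#'
#' @param track data frame with `distance_km` (or `lat`/`lon`) and
#'   `abundance_cells_per_ml`; optional `temperature_C`, `lat`, `lon`,
#'   `time_iso8601`.
#' @param spacing grid spacing in km (default 5).
#' @param max_gap maximum raw gap interpolated across, km (default 100).
#' @return list of uniform `cruise_track` data frames (attribute
#'   `"spacing_km"` set), one per segment; segments with fewer than 2 raw
#'   samples are dropped.
#' @export
interpolate_track <- function(track, spacing = 5, max_gap = 100) {
  check_positive(spacing, "spacing")
  check_positive(max_gap, "max_gap")
  track <- as_track(track)
  if (nrow(track) < 2) stop("track needs at least 2 samples")
  gaps <- diff(track$distance_km)
  seg_id <- cumsum(c(1, as.integer(gaps > max_gap)))
  segs <- split(seq_len(nrow(track)), seg_id)
  out <- list()
  numeric_cols <- intersect(c("temperature_C", "lat", "lon", "par"), names(track))
  for (idx in segs) {
    if (length(idx) < 2) next
    d <- track$distance_km[idx]
    grid <- seq(d[1], d[length(d)], by = spacing)
    seg <- data.frame(distance_km = grid)
    seg$abundance_cells_per_ml <-
      stats::approx(d, track$abundance_cells_per_ml[idx], xout = grid)$y
    for (cc in numeric_cols)
      seg[[cc]] <- stats::approx(d, track[[cc]][idx], xout = grid)$y
    if ("time_iso8601" %in% names(track)) {
      tt <- as.numeric(as.POSIXct(track$time_iso8601[idx], tz = "UTC"))
      seg$time_iso8601 <- format(
        as.POSIXct(stats::approx(d, tt, xout = grid)$y,
                   origin = "1970-01-01", tz = "UTC"),
        "%Y-%m-%dT%H:%M:%SZ")
    }
    if ("cruise_id" %in% names(track)) seg$cruise_id <- track$cruise_id[idx[1]]
    class(seg) <- c("cruise_track", "data.frame")
    attr(seg, "spacing_km") <- spacing
    out[[length(out) + 1]] <- seg
  }
  out
}

# Grid half-width in samples for a wavelet half-width alpha on spacing d.
haar_halfwidth <- function(alpha, spacing) max(1L, as.integer(round(alpha / spacing)))

#' Haar sustained-change statistic along a uniform track
#'
#' Convolves the signal with a step-shaped (Haar) window of half-width
#' `alpha`: at each position `t`,
#' `S(t) = (mean of f over [t, t + alpha) - mean of f over [t - alpha, t)) / alpha`,
#' which measures the change in `f` sustained over `[t - alpha, t + alpha]`
#' per km. On a linear ramp `S` equals the ramp slope exactly, and at an
#' ideal step of height `h` the peak is `h / alpha`, so the statistic has
#' units of cells/mL/km and a filter threshold expressed in those units
#' applies directly. Positive `S` means abundance increases in the travel
#' direction.
#'
#' On the discrete grid the two windows are the `w = round(alpha/spacing)`
#' samples on each side of `t` (left window includes `t - alpha` up to but
#' excluding `t`; right window includes `t` up to but excluding
#' `t + alpha`), and the effective half-width `w * spacing` is used in the
#' denominator. `S` is only evaluated at positions with full window
#' support.
#'
#' @param segment uniform `cruise_track` (from [interpolate_track()] or
#'   [generate_cruise_track()]), or a data frame with `distance_km` at
#'   uniform spacing and `abundance_cells_per_ml`.
#' @param alpha wavelet half-width in km (default 150).
#' @param values optional numeric vector to transform instead of the
#'   abundance column (e.g. temperature).
#' @param normalization multiplicative rescaling of the wavelet (default
#'   1). Correlation-based downstream statistics are invariant to it.
#' @return data frame with `distance_km` and `statistic`; zero rows (with a
#'   warning) when the segment is shorter than `2 * alpha`.
#' @export
haar_statistic <- function(segment, alpha = 150, values = NULL,
                           normalization = 1) {
  check_positive(alpha, "alpha")
  d <- segment$distance_km
  f <- if (is.null(values)) segment$abundance_cells_per_ml else values
  n <- length(f)
  spacing <- attr(segment, "spacing_km")
  if (is.null(spacing)) {
    steps <- diff(d)
    if (length(steps) && max(abs(steps - steps[1])) > 1e-6 * steps[1])
      stop("segment is not uniformly spaced; run interpolate_track() first")
    spacing <- steps[1]
  }
  w <- haar_halfwidth(alpha, spacing)
  if (n < 2 * w + 1) {
    warning("segment shorter than twice the wavelet half-width; empty profile")
    return(data.frame(distance_km = numeric(), statistic = numeric()))
  }
  alpha_eff <- w * spacing
  cs <- c(0, cumsum(f))
  # windows: left = samples [i-w, i-1], right = samples [i, i+w-1]
  i <- (w + 1L):(n - w + 1L)
  right_mean <- (cs[i + w] - cs[i]) / w
  left_mean <- (cs[i] - cs[i - w]) / w
  s <- normalization * (right_mean - left_mean) / alpha_eff
  data.frame(distance_km = d[i], statistic = s)
}

# Local extrema of |S| at or above the filter threshold, then greedy
# suppression: keep the largest |S| among candidates closer than
# min_separation (ties -> smaller position).
peak_positions <- function(profile, filter_threshold, min_separation) {
  s <- profile$statistic
  n <- length(s)
  if (n < 3) return(integer())
  a <- abs(s)
  is_peak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n],
               FALSE) & a >= filter_threshold
  # collapse flat plateaus to their first sample
  cand <- which(is_peak)
  if (length(cand) > 1) {
    drop <- c(FALSE, diff(cand) == 1 & abs(diff(a[cand])) < .Machine$double.eps)
    cand <- cand[!drop]
  }
  if (!length(cand)) return(integer())
  ord <- cand[order(-a[cand], profile$distance_km[cand])]
  kept <- integer()
  for (j in ord) {
    if (!length(kept) ||
        all(abs(profile$distance_km[kept] - profile$distance_km[j]) >= min_separation))
      kept <- c(kept, j)
  }
  sort(kept)
}

#' Scalogram: Haar statistic across wavelet widths
#'
#' Evaluates the Haar profile for each half-width in `alphas` and counts
#' the surviving peaks (filter threshold plus minimum-separation rule) per
#' width — the stability scan used to choose a working `alpha`: peak counts
#' fall sharply as the width grows from 0 and stabilize near 150 km.
#'
#' @param segment uniform `cruise_track`.
#' @param alphas ascending positive half-widths, km.
#' @param params [haar_params()] supplying the filter threshold and
#'   separation rule.
#' @return list with `alphas`, `profiles` (one Haar profile per alpha),
#'   `matrix` (positions x alphas, `NA` outside support) and `peak_counts`.
#' @export
scalogram <- function(segment, alphas = seq(10, 300, by = 10),
                      params = haar_params()) {
  if (any(alphas <= 0) || is.unsorted(alphas, strictly = TRUE))
    stop("alphas must be positive and strictly ascending")
  profiles <- lapply(alphas, function(a)
    suppressWarnings(haar_statistic(segment, alpha = a)))
  counts <- vapply(profiles, function(p)
    length(peak_positions(p, params$filter_threshold, params$min_separation)),
    integer(1))
  pos <- segment$distance_km
  mat <- matrix(NA_real_, nrow = length(pos), ncol = length(alphas),
                dimnames = list(NULL, paste0("alpha_", alphas)))
  for (k in seq_along(alphas)) {
    p <- profiles[[k]]
    if (nrow(p)) mat[match(p$distance_km, pos), k] <- p$statistic
  }
  list(alphas = alphas, profiles = profiles, matrix = mat,
       peak_counts = counts)
}

#' Detect sustained abundance transitions along a track
#'
#' Applies the Haar statistic at half-width `params$alpha`, keeps local
#' extrema with `|S|` at or above `params$filter_threshold`, enforces the
#' minimum separation rule (largest `|S|` wins; ties break toward the
#' smaller position), and flags whether the flanking-window mean abundances
#' straddle `params$regime_threshold` — i.e. whether the shift crosses
#' between high- and low-abundance regimes rather than fluctuating within
#' one.
#'
#' @param segment uniform `cruise_track` segment.
#' @param params [haar_params()].
#' @return data frame of class `transition_table`: `cruise_id`,
#'   `distance_km`, `lat`, `lon`, `time_iso8601`, `statistic`,
#'   `left_mean`, `right_mean`, `crosses_regime_threshold`. Zero rows when
#'   nothing passes the filter.
#' @export
detect_transitions <- function(segment, params = haar_params()) {
  stopifnot(inherits(params, "haar_params"))
  prof <- suppressWarnings(haar_statistic(segment, alpha = params$alpha))
  empty <- data.frame(cruise_id = character(), distance_km = numeric(),
                      lat = numeric(), lon = numeric(),
                      time_iso8601 = character(), statistic = numeric(),
                      left_mean = numeric(), right_mean = numeric(),
                      crosses_regime_threshold = logical())
  class(empty) <- c("transition_table", "data.frame")
  if (!nrow(prof)) return(empty)
  idx <- peak_positions(prof, params$filter_threshold, params$min_separation)
  if (!length(idx)) return(empty)

  spacing <- attr(segment, "spacing_km")
  if (is.null(spacing)) spacing <- diff(segment$distance_km[1:2])
  w <- haar_halfwidth(params$alpha, spacing)
  f <- segment$abundance_cells_per_ml
  cs <- c(0, cumsum(f))
  seg_i <- match(prof$distance_km[idx], segment$distance_km)
  left_mean <- (cs[seg_i] - cs[seg_i - w]) / w
  right_mean <- (cs[seg_i + w] - cs[seg_i]) / w
  crosses <- (left_mean < params$regime_threshold) !=
    (right_mean < params$regime_threshold)

  out <- data.frame(
    cruise_id = if ("cruise_id" %in% names(segment))
      segment$cruise_id[seg_i] else NA_character_,
    distance_km = prof$distance_km[idx],
    lat = if ("lat" %in% names(segment)) segment$lat[seg_i] else NA_real_,
    lon = if ("lon" %in% names(segment)) segment$lon[seg_i] else NA_real_,
    time_iso8601 = if ("time_iso8601" %in% names(segment))
      segment$time_iso8601[seg_i] else NA_character_,
    statistic = prof$statistic[idx],
    left_mean = left_mean, right_mean = right_mean,
    crosses_regime_threshold = crosses
  )
  class(out) <- c("transition_table", "data.frame")
  out
}

#' Attach satellite temperature and PAR to detected transitions
#'
#' Colocalizes each transition's position and date against gridded fields
#' under the same tolerance rules as [colocalize_records()]. Unmatched
#' transitions are retained with missing values and flagged, so a sparse
#' satellite day never silently removes a detection.
#'
#' @param transitions a `transition_table` from [detect_transitions()].
#' @param temperature_field,par_field [gridded_field()] objects (either may
#'   be `NULL`).
#' @param ... tolerances passed to [colocalize_records()].
#' @return the transitions with `temperature_C`, `par` and a logical
#'   `colocalized` column.
#' @export
colocalize_transitions <- function(transitions, temperature_field = NULL,
                                   par_field = NULL, ...) {
  if (!nrow(transitions)) {
    transitions$temperature_C <- numeric()
    transitions$par <- numeric()
    transitions$colocalized <- logical()
    return(transitions)
  }
  obs <- data.frame(lat = transitions$lat, lon = transitions$lon,
                    depth_m = 0, time_iso8601 = transitions$time_iso8601,
                    row = seq_len(nrow(transitions)))
  matched <- suppressWarnings(
    colocalize_records(obs, temperature_field, par_field, ...))
  transitions$temperature_C <- NA_real_
  transitions$par <- NA_real_
  if (nrow(matched)) {
    if ("temperature_C" %in% names(matched))
      transitions$temperature_C[matched$row] <- matched$temperature_C
    if ("par" %in% names(matched))
      transitions$par[matched$row] <- matched$par
  }
  transitions$colocalized <- seq_len(nrow(transitions)) %in% matched$row
  transitions
}

#' Scale-dependent correlation between abundance and temperature
#'
#' For each spatial scale `lambda`, filters both the abundance and the
#' temperature series of every track with the Haar statistic at half-width
#' `lambda / 2`, pools the filtered values across all tracks and segments,
#' and reports the squared Pearson correlation between the two pooled
#' series. Scales with fewer than `min_points` pooled values are reported
#' as `NA`. Because Pearson correlation is invariant to rescaling either
#' series, the curve does not depend on how the wavelet is normalized.
#'
#' A ramp in this curve — low R-squared at short scales rising at scales
#' that span transitions between abundance regimes — indicates that the
#' temperature-abundance association lives at the regime boundaries, not
#' in local fluctuations.
#'
#' @param tracks list of uniform `cruise_track` segments carrying both
#'   `abundance_cells_per_ml` and `temperature_C`.
#' @param scales strictly increasing spatial scales in km; default 16
#'   log-spaced scales from 10 to 3000 km.
#' @param min_points minimum pooled points per scale (default 10).
#' @param normalization wavelet rescaling passed through to
#'   [haar_statistic()] (default 1; provably irrelevant to R-squared).
#' @return data frame of class `scale_correlation_curve` with `scale_km`,
#'   `r_squared`, `n_points`.
#' @export
scale_correlation <- function(tracks,
                              scales = round(exp(seq(log(10), log(3000),
                                                     length.out = 16))),
                              min_points = 10, normalization = 1) {
  if (inherits(tracks, "data.frame")) tracks <- list(tracks)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be positive and strictly increasing")
  for (tr in tracks)
    if (!"temperature_C" %in% names(tr))
      stop("every track must carry a 'temperature_C' column")
  r2 <- rep(NA_real_, length(scales))
  npts <- integer(length(scales))
  for (k in seq_along(scales)) {
    a <- scales[k] / 2
    sa <- list(); st <- list()
    for (tr in tracks) {
      pa <- suppressWarnings(haar_statistic(tr, alpha = a,
                                            normalization = normalization))
      if (!nrow(pa)) next
      pt <- suppressWarnings(haar_statistic(tr, alpha = a,
                                            values = tr$temperature_C,
                                            normalization = normalization))
      sa[[length(sa) + 1]] <- pa$statistic
      st[[length(st) + 1]] <- pt$statistic
    }
    x <- unlist(sa); y <- unlist(st)
    npts[k] <- length(x)
    if (length(x) >= min_points && stats::sd(x) > 0 && stats::sd(y) > 0)
      r2[k] <- stats::cor(x, y)^2
  }
  out <- data.frame(scale_km = scales, r_squared = r2, n_points = npts)
  class(out) <- c("scale_correlation_curve", "data.frame")
  out
}

#' @export
plot.scale_correlation_curve <- function(x, ...) {
  ok <- !is.na(x$r_squared)
  graphics::plot(x$scale_km[ok], x$r_squared[ok], log = "x", type = "b",
                 pch = 16, xlab = "spatial scale (km)",
                 ylab = expression(R^2), ylim = c(0, 1), ...)
  invisible(x)
}
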