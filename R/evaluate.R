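# Head-to-head evaluation of abundance models: residuals in linear and
# log space, R^2 and residual variance, variance ratios, latitudinal
# residual profiles and latitude-band subsetting.

#' Model residuals in linear or log space
#'
#' Residual = transformed observation minus transformed prediction. Log
#' space applies [log10_clip()] to both sides first, so observed zeros
#' contribute 0 rather than -Inf.
#'
#' @param predictions,observations abundance vectors of equal length,
#'   cells/mL.
#' @param space `"linear"` or `"log"`.
#' @return numeric residual vector.
#' @export
model_residuals <- function(predictions, observations,
                            space = c("linear", "log")) {
  space <- match.arg(space)
  if (length(predictions) != length(observations))
    stop("predictions and observations must have equal length")
  if (space == "log") log10_clip(observations) - log10_clip(predictions)
  else observations - predictions
}

#' Goodness of fit of abundance predictions
#'
#' `r_squared = 1 - SS_res / SS_tot` with the total sum of squares about
#' the observation mean in the chosen space. This convention (rather than
#' squared correlation) penalizes miscalibrated models and can go
#' negative; the two coincide for least-squares-fitted models.
#' `residual_variance` is the population variance (divisor `n`) of the
#' residuals.
#'
#' @param predictions,observations abundance vectors, length at least 2.
#' @param space `"linear"` or `"log"`.
#' @return list with `r_squared` (`NA` when the observations have zero
#'   variance), `residual_variance`, `n`, `space`.
#' @export
goodness <- function(predictions, observations, space = c("linear", "log")) {
  space <- match.arg(space)
  if (length(observations) < 2) stop("need at least 2 observations")
  r <- model_residuals(predictions, observations, space)
  y <- if (space == "log") log10_clip(observations) else observations
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) NA_real_ else 1 - sum(r^2) / ss_tot
  list(r_squared = r2,
       residual_variance = sum((r - mean(r))^2) / n,
       n = n, space = space)
}

#' Compare two abundance models on the same observations
#'
#' Evaluates both prediction sets in linear and log space and reports the
#' residual-variance ratio a/b per space. A ratio below 1 means model A's
#' residuals have less variance; a ratio of about 0.85, for instance,
#' corresponds to model A explaining ~15% more residual variance than
#' model B.
#'
#' @param predictions_a,predictions_b abundance predictions, cells/mL.
#' @param observations observed abundances, cells/mL.
#' @param names_ab character vector of 2 model names for the summary rows.
#' @return list of class `model_comparison`: `summary` (one row per model
#'   and space: `model`, `space`, `n`, `r_squared`, `residual_variance`)
#'   and `variance_ratio` (named vector, `NA` where model B's residual
#'   variance is 0).
#' @export
compare_models <- function(predictions_a, predictions_b, observations,
                           names_ab = c("model_a", "model_b")) {
  n <- length(observations)
  if (length(predictions_a) != n || length(predictions_b) != n)
    stop("all inputs must have equal length")
  rows <- list(); ratio <- c(linear = NA_real_, log = NA_real_)
  for (sp in c("linear", "log")) {
    ga <- goodness(predictions_a, observations, sp)
    gb <- goodness(predictions_b, observations, sp)
    rows[[length(rows) + 1]] <- data.frame(
      model = names_ab, space = sp, n = n,
      r_squared = c(ga$r_squared, gb$r_squared),
      residual_variance = c(ga$residual_variance, gb$residual_variance))
    ratio[sp] <- if (gb$residual_variance > 0)
      ga$residual_variance / gb$residual_variance else NA_real_
  }
  structure(list(summary = do.call(rbind, rows), variance_ratio = ratio),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("residual-variance ratio (a/b): linear %.3f, log %.3f\n",
              x$variance_ratio["linear"], x$variance_ratio["log"]))
  invisible(x)
}

#' Mean residual by latitude band
#'
#' Bins residuals into half-open latitude bands `[edge, edge + width)`
#' anchored at -90 and reports each represented band's mean residual —
#' the latitudinal profile that localizes where a model's bias lives.
#'
#' @param residuals numeric residual vector.
#' @param lat matching latitudes in degrees.
#' @param band_width band width in degrees (default 10).
#' @return data frame with `lat_min`, `lat_max`, `mean_residual`, `n`;
#'   empty bands omitted.
#' @export
latitude_profile <- function(residuals, lat, band_width = 10) {
  check_positive(band_width, "band_width")
  if (length(residuals) != length(lat)) stop("residuals and lat lengths differ")
  check_lat(lat)
  band <- floor((lat + 90) / band_width)
  ub <- sort(unique(band))
  data.frame(
    lat_min = -90 + ub * band_width,
    lat_max = -90 + (ub + 1) * band_width,
    mean_residual = vapply(ub, function(b) mean(residuals[band == b]), numeric(1)),
    n = vapply(ub, function(b) sum(band == b), integer(1))
  )
}

#' Subset observations to a latitude band
#'
#' Inclusive at both endpoints, so e.g. the 30 degS - 30 degN tropical
#' band retains records at exactly 30 degrees.
#'
#' @param observations data frame with a `lat` column.
#' @param lat_min,lat_max band limits in degrees, `lat_min < lat_max`.
#' @return the retained rows, order preserved.
#' @export
subset_band <- function(observations, lat_min, lat_max) {
  if (!is.numeric(lat_min) || !is.numeric(lat_max) || lat_min >= lat_max)
    stop("need lat_min < lat_max")
  observations[observations$lat >= lat_min & observations$lat <= lat_max, ,
               drop = FALSE]
}
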