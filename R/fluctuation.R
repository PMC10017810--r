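# Station time-series stage: cruise averaging, monthly binning,
# consecutive-month differencing, bootstrap correlation statistics,
# quadrant analysis and the two-predictor R^2.

#' Per-cruise means of station measurements
#'
#' Averages temperature, PAR and abundance over each cruise's surface
#' records (arithmetic mean over non-missing values) and assigns each
#' cruise the median of its sampling dates, which is robust for multi-day
#' cruises. Records must already be surface-filtered; any depth beyond
#' 50 m is rejected so deep casts cannot leak into surface means.
#'
#' @param records data frame with `cruise_id`, `time_iso8601`, `depth_m`,
#'   and any of `temperature_C`, `par`, `abundance_cells_per_ml`.
#' @return data frame with one row per cruise: `cruise_id`, `date`,
#'   `temperature_C`, `par`, `abundance_cells_per_ml`, `n_records`.
#'   Cruises with no usable (non-missing) values are omitted with a
#'   warning.
#' @export
cruise_means <- function(records) {
  need <- c("cruise_id", "time_iso8601", "depth_m")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$depth_m > 50, na.rm = TRUE))
    stop("records deeper than 50 m present; apply filter_surface() first")
  vars <- intersect(c("temperature_C", "par", "abundance_cells_per_ml"),
                    names(records))
  if (!length(vars)) stop("no measurement columns found")
  ids <- unique(records$cruise_id)
  rows <- lapply(ids, function(id) {
    r <- records[records$cruise_id == id, , drop = FALSE]
    means <- vapply(vars, function(v) {
      x <- r[[v]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(means))) return(NULL)
    dt <- sort(as.Date(as.POSIXct(r$time_iso8601, tz = "UTC")))
    out <- data.frame(cruise_id = id,
                      date = dt[ceiling(length(dt) / 2)],
                      n_records = nrow(r))
    for (v in vars) out[[v]] <- means[[v]]
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " cruise(s) had no usable measurements and were omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cruise_id = character(), date = as.Date(character()),
                      n_records = integer())
  rownames(out) <- NULL
  out
}

#' Bin cruise means into calendar months
#'
#' One record per calendar year-month represented among the cruises;
#' values are means over the cruises falling in that month. Months with no
#' cruise are simply absent (no imputation).
#'
#' @param cruises output of [cruise_means()].
#' @return data frame of class `station_monthly` with `year_month`,
#'   measurement means and `n_cruises`.
#' @export
monthly_bin <- function(cruises) {
  vars <- intersect(c("temperature_C", "par", "abundance_cells_per_ml"),
                    names(cruises))
  if (!nrow(cruises)) {
    out <- data.frame(year_month = character(), n_cruises = integer())
    for (v in vars) out[[v]] <- numeric()
    class(out) <- c("station_monthly", "data.frame")
    return(out)
  }
  ym <- format(cruises$date, "%Y-%m")
  uym <- sort(unique(ym))
  rows <- lapply(uym, function(m) {
    r <- cruises[ym == m, , drop = FALSE]
    out <- data.frame(year_month = m, n_cruises = nrow(r))
    for (v in vars) out[[v]] <- mean(r[[v]], na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("station_monthly", "data.frame")
  out
}

#' Differences between consecutive represented months
#'
#' One delta per pair of adjacent calendar months that are both
#' represented; a gap month produces no delta, and December to January
#' across a year boundary counts as consecutive.
#'
#' @param monthly a `station_monthly` data frame (sorted by `year_month`).
#' @return data frame of class `monthly_deltas` with `from_month`,
#'   `to_month`, `dT`, `dPAR`, `dPro`.
#' @export
consecutive_deltas <- function(monthly) {
  empty <- data.frame(from_month = character(), to_month = character(),
                      dT = numeric(), dPAR = numeric(), dPro = numeric())
  class(empty) <- c("monthly_deltas", "data.frame")
  if (!nrow(monthly)) return(empty)
  ord <- order(monthly$year_month)
  monthly <- monthly[ord, , drop = FALSE]
  mi <- month_index(monthly$year_month)
  if (anyDuplicated(mi)) stop("duplicate year_month entries")
  adj <- which(diff(mi) == 1L)
  if (!length(adj)) return(empty)
  getd <- function(v) if (v %in% names(monthly))
    monthly[[v]][adj + 1L] - monthly[[v]][adj] else rep(NA_real_, length(adj))
  out <- data.frame(
    from_month = monthly$year_month[adj],
    to_month = monthly$year_month[adj + 1L],
    dT = getd("temperature_C"),
    dPAR = getd("par"),
    dPro = getd("abundance_cells_per_ml")
  )
  class(out) <- c("monthly_deltas", "data.frame")
  out
}

# Vectorized paired bootstrap of the Pearson correlation: returns the
# resampled correlations (NA where a resample is degenerate).
boot_cor <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  mx <- colMeans(xb); my <- colMeans(yb)
  sxy <- colMeans(xb * yb) - mx * my
  sxx <- colMeans(xb * xb) - mx^2
  syy <- colMeans(yb * yb) - my^2
  r <- sxy / sqrt(sxx * syy)
  r[sxx <= 0 | syy <= 0] <- NA_real_
  r
}

#' Pearson correlation with bootstrap uncertainty
#'
#' Sample Pearson correlation of two paired series, with its uncertainty
#' estimated as the standard deviation of the correlation over `n_boot`
#' paired nonparametric bootstrap resamples (degenerate zero-variance
#' resamples are discarded). A closed-form alternative, the Fisher
#' transform large-sample standard error `1 / sqrt(n - 3)`, is available
#' via `method = "fisher"`.
#'
#' @param x,y numeric series of equal length, at least 3.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @param method `"bootstrap"` (default) or `"fisher"`.
#' @return object of class `cor_result`: `estimate`, `se`, `r_squared`,
#'   `n`, `n_boot`, `seed`, `method`.
#' @export
pearson_boot <- function(x, y, n_boot = 1000, seed = 1,
                         method = c("bootstrap", "fisher")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("series must be finite")
  if (stats::sd(x) == 0) stop("series 'x' has zero variance")
  if (stats::sd(y) == 0) stop("series 'y' has zero variance")
  est <- stats::cor(x, y)
  se <- if (method == "fisher") {
    # delta-method back-transform of the Fisher-z SE
    (1 - est^2) / sqrt(length(x) - 3)
  } else {
    rb <- with_seed(seed, boot_cor(x, y, n_boot))
    stats::sd(rb[is.finite(rb)])
  }
  structure(list(estimate = est, se = se, r_squared = est^2, n = length(x),
                 n_boot = if (method == "bootstrap") n_boot else NA_integer_,
                 seed = seed, method = method),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f +/- %.3f (R^2 = %.3f, n = %d, %s)\n",
              x$estimate, x$se, x$r_squared, x$n, x$method))
  invisible(x)
}

#' Quadrant analysis of monthly deltas
#'
#' Classifies each delta by the signs of `(dT, dPAR)` — the lower-right
#' quadrant is warming with dimming (`dT > 0, dPAR < 0`), the upper-left
#' cooling with brightening — and reports, per quadrant and overall, the
#' fraction of months in which abundance increased (`dPro > 0` strictly).
#' Zero-valued `dT` or `dPAR` deltas belong to no quadrant. Uncertainties
#' are bootstrap standard errors of each fraction (resampling deltas with
#' replacement).
#'
#' @param deltas a `monthly_deltas` data frame (non-empty).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return data frame with rows `lower_right`, `upper_left`, `upper_right`,
#'   `lower_left`, `overall`: columns `n`, `fraction_increasing`, `se`.
#'   Empty quadrants report `n = 0` and `NA` fraction.
#' @export
quadrant_fractions <- function(deltas, n_boot = 1000, seed = 1) {
  if (!nrow(deltas)) stop("deltas must be non-empty")
  quad <- function(dT, dPAR) {
    q <- rep(NA_character_, length(dT))
    q[dT > 0 & dPAR < 0] <- "lower_right"
    q[dT < 0 & dPAR > 0] <- "upper_left"
    q[dT > 0 & dPAR > 0] <- "upper_right"
    q[dT < 0 & dPAR < 0] <- "lower_left"
    q
  }
  quads <- c("lower_right", "upper_left", "upper_right", "lower_left", "overall")
  frac_by_quad <- function(d) {
    q <- quad(d$dT, d$dPAR)
    up <- d$dPro > 0
    vapply(quads, function(nm) {
      sel <- if (nm == "overall") rep(TRUE, nrow(d)) else !is.na(q) & q == nm
      if (!any(sel)) NA_real_ else mean(up[sel])
    }, numeric(1))
  }
  point <- frac_by_quad(deltas)
  q <- quad(deltas$dT, deltas$dPAR)
  ns <- vapply(quads, function(nm)
    if (nm == "overall") nrow(deltas) else sum(!is.na(q) & q == nm), integer(1))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      frac_by_quad(deltas[sample.int(nrow(deltas), replace = TRUE), ,
                          drop = FALSE])
    }, numeric(length(quads)))
  })
  se <- apply(boot, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) else NA_real_
  })
  data.frame(quadrant = quads, n = ns, fraction_increasing = point, se = se,
             row.names = NULL)
}

#' Two-predictor R-squared of abundance changes
#'
#' Ordinary least-squares fit `dPro ~ dT + dPAR`; reports the fit's
#' R-squared with a bootstrap standard error — the multivariate analogue
#' of the single-variable delta correlations.
#'
#' @param deltas a `monthly_deltas` data frame with at least 4 rows.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return object of class `cor_result` whose `estimate` is `NA` (no
#'   single signed coefficient) and whose `r_squared`/`se` carry the
#'   statistic; also holds `coefficients` of the OLS fit.
#' @export
bivariate_r2 <- function(deltas, n_boot = 1000, seed = 1) {
  if (nrow(deltas) < 4) stop("need at least 4 deltas")
  if (stats::sd(deltas$dT) == 0 || stats::sd(deltas$dPAR) == 0 ||
      abs(stats::cor(deltas$dT, deltas$dPAR)) >= 1 - 1e-12)
    stop("dT and dPAR are perfectly collinear; the two-predictor fit is undefined")
  fit <- stats::lm(dPro ~ dT + dPAR, data = deltas)
  r2 <- summary(fit)$r.squared
  rb <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      d <- deltas[sample.int(nrow(deltas), replace = TRUE), , drop = FALSE]
      if (stats::sd(d$dT) == 0 || stats::sd(d$dPAR) == 0 ||
          abs(stats::cor(d$dT, d$dPAR)) >= 1 - 1e-12) return(NA_real_)
      suppressWarnings(summary(stats::lm(dPro ~ dT + dPAR, data = d))$r.squared)
    }, numeric(1))
  })
  structure(list(estimate = NA_real_, se = stats::sd(rb[is.finite(rb)]),
                 r_squared = r2, n = nrow(deltas), n_boot = n_boot,
                 seed = seed, method = "bootstrap",
                 coefficients = stats::coef(fit)),
            class = "cor_result")
}
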