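# The two-state threshold niche model: zero abundance below a viability
# temperature, a fitted constant above it. This is the package's core
# estimator; everything else diagnoses it.

#' Log-abundance with the zero convention
#'
#' `log10(max(x, 1))`: abundances are clipped at 1 cell/mL before the log,
#' so zero measurements map to 0 in log space. This is the convention used
#' for all log-space residuals and goodness-of-fit statistics here.
#'
#' @param abundance non-negative abundances (cells/mL).
#' @return log10 abundances; monotone non-decreasing in `abundance`.
#' @examples
#' log10_clip(c(0, 0.5, 1, 1000))  # 0 0 0 3
#' @export
log10_clip <- function(abundance) {
  check_nonnegative(abundance, "abundance")
  log10(pmax(abundance, 1))
}

new_two_state <- function(t_threshold, c_high, extra = list()) {
  stopifnot(is.finite(t_threshold), is.finite(c_high))
  if (c_high < 0) stop("c_high must be non-negative")
  structure(c(list(t_threshold = t_threshold, c_high = c_high), extra),
            class = "two_state")
}

#' Construct a two-state threshold model
#'
#' A step-function species distribution model: predicted abundance is
#' `c_high` cells/mL where temperature is at or above `t_threshold`
#' (boundary inclusive) and 0 below it.
#'
#' @param t_threshold viability temperature threshold in deg C (default 13).
#' @param c_high constant abundance in the viable state, cells/mL
#'   (default 42000).
#' @return an object of class `two_state`.
#' @seealso [fit_two_state()] to estimate `c_high` from observations.
#' @examples
#' m <- two_state()
#' predict(m, temperature = c(12.99, 13, 30))
#' @export
two_state <- function(t_threshold = 13, c_high = 42000) {
  new_two_state(t_threshold, c_high)
}

#' Fit the two-state model to surface observations
#'
#' Estimates the viable-state constant `c_high` at a fixed temperature
#' threshold. The default objective minimizes the variance of the residuals
#' `r = abundance - prediction`; its closed-form minimizer is the difference
#' of conditional means,
#' `c_high = mean(abundance | T >= threshold) - mean(abundance | T < threshold)`,
#' clamped at 0 (differentiating `Var(r)` in `c_high` gives this directly,
#' since the prediction is `c_high` times the above-threshold indicator).
#' The `"mse"` objective minimizes mean squared error instead, giving
#' `c_high = mean(abundance | T >= threshold)`. The two coincide when all
#' below-threshold abundances are zero.
#'
#' The fit is performed in linear space (cells/mL) by default; with
#' `space = "log"` the conditional means are taken on [log10_clip()]
#' transformed abundances and the fitted constant is back-transformed.
#'
#' @param data data frame with columns `temperature_C` and
#'   `abundance_cells_per_ml`, or a numeric abundance vector if
#'   `temperature` is supplied.
#' @param t_threshold temperature threshold in deg C, held fixed (default 13).
#' @param objective `"variance"` (default) or `"mse"`.
#' @param space `"linear"` (default) or `"log"`.
#' @param temperature optional numeric temperature vector when `data` is a
#'   plain abundance vector.
#' @return a `two_state` model object carrying the fit (data summaries,
#'   fitted values and residuals accessible via methods).
#' @examples
#' d <- data.frame(temperature_C = c(5, 6, 20, 25),
#'                 abundance_cells_per_ml = c(0, 100, 40000, 44000))
#' fit <- fit_two_state(d)
#' coef(fit)   # c_high = 42000 - 50 = 41950
#' @export
fit_two_state <- function(data, t_threshold = 13,
                          objective = c("variance", "mse"),
                          space = c("linear", "log"),
                          temperature = NULL) {
  objective <- match.arg(objective)
  space <- match.arg(space)
  if (is.data.frame(data)) {
    need <- c("temperature_C", "abundance_cells_per_ml")
    miss <- setdiff(need, names(data))
    if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
    temp <- data$temperature_C
    ab <- data$abundance_cells_per_ml
  } else {
    if (is.null(temperature)) stop("supply 'temperature' when data is not a data frame")
    temp <- temperature; ab <- as.numeric(data)
  }
  ok <- is.finite(temp) & is.finite(ab)
  temp <- temp[ok]; ab <- ab[ok]
  if (length(ab) == 0) stop("no usable observations to fit")
  check_nonnegative(ab, "abundance")
  if (!is.finite(t_threshold)) stop("t_threshold must be finite")

  above <- temp >= t_threshold
  if (!any(above))
    stop("no observations with temperature >= threshold (", t_threshold, " degC)")

  y <- if (space == "log") log10_clip(ab) else ab
  mean_above <- mean(y[above])
  mean_below <- if (any(!above)) mean(y[!above]) else NA_real_

  c_fit <- if (objective == "mse" || !any(!above)) mean_above
           else mean_above - mean_below
  c_fit <- max(c_fit, 0)
  c_high <- if (space == "log") 10^c_fit else c_fit

  m <- new_two_state(
    t_threshold, c_high,
    extra = list(
      objective = objective, space = space,
      n = length(ab), n_above = sum(above), n_below = sum(!above),
      mean_above = mean_above, mean_below = mean_below,
      data = data.frame(temperature_C = temp, abundance_cells_per_ml = ab),
      call = match.call()
    )
  )
  m
}

#' Predict abundance from a two-state model
#'
#' @param object a `two_state` model.
#' @param newdata data frame with a `temperature_C` column, or omitted to
#'   predict on the training data.
#' @param temperature numeric temperatures in deg C (alternative to
#'   `newdata`).
#' @param ... unused.
#' @return predicted abundances (cells/mL): `c_high` where
#'   `temperature >= t_threshold`, else 0.
#' @export
predict.two_state <- function(object, newdata = NULL, temperature = NULL, ...) {
  temp <- if (!is.null(temperature)) temperature
  else if (!is.null(newdata)) {
    if (is.data.frame(newdata)) newdata$temperature_C else as.numeric(newdata)
  } else if (!is.null(object$data)) object$data$temperature_C
  else stop("supply 'newdata' or 'temperature'")
  if (any(is.na(temp))) stop("temperature contains missing values")
  if (any(!is.finite(temp))) stop("temperature must be finite")
  ifelse(temp >= object$t_threshold, object$c_high, 0)
}

#' @export
coef.two_state <- function(object, ...) {
  c(t_threshold = object$t_threshold, c_high = object$c_high)
}

#' Residuals of a two-state fit
#'
#' @param object a fitted `two_state` model (from [fit_two_state()]).
#' @param space `"linear"` residuals in cells/mL or `"log"` residuals on the
#'   [log10_clip()] scale.
#' @param ... unused.
#' @return observed minus predicted, in the chosen space.
#' @export
residuals.two_state <- function(object, space = c("linear", "log"), ...) {
  space <- match.arg(space)
  if (is.null(object$data)) stop("model carries no training data")
  obs <- object$data$abundance_cells_per_ml
  pred <- predict(object)
  if (space == "log") log10_clip(obs) - log10_clip(pred) else obs - pred
}

#' @export
fitted.two_state <- function(object, ...) predict(object)

#' @export
print.two_state <- function(x, ...) {
  cat("Two-state threshold niche model\n")
  cat(sprintf("  threshold: %g degC (fixed)\n", x$t_threshold))
  cat(sprintf("  c_high:    %g cells/mL%s\n", x$c_high,
              if (!is.null(x$objective))
                sprintf(" (objective: %s, %s space)", x$objective, x$space) else ""))
  if (!is.null(x$n))
    cat(sprintf("  fitted on %d observations (%d above / %d below threshold)\n",
                x$n, x$n_above, x$n_below))
  invisible(x)
}

#' @export
summary.two_state <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$data)) {
    for (sp in c("linear", "log")) {
      r <- residuals(object, space = sp)
      obs <- object$data$abundance_cells_per_ml
      y <- if (sp == "log") log10_clip(obs) else obs
      g <- goodness(predict(object), obs, space = sp)
      out[[paste0("goodness_", sp)]] <- g
    }
  }
  class(out) <- "summary.two_state"
  out
}

#' @export
print.summary.two_state <- function(x, ...) {
  print(x$model)
  if (!is.null(x$goodness_linear)) {
    cat(sprintf("  R^2 (linear): %.4f   residual variance: %.4g\n",
                x$goodness_linear$r_squared, x$goodness_linear$residual_variance))
    cat(sprintf("  R^2 (log):    %.4f   residual variance: %.4g\n",
                x$goodness_log$r_squared, x$goodness_log$residual_variance))
  }
  invisible(x)
}

#' Simulate abundances from a two-state model
#'
#' Draws from the model's generative form: in the viable state, `c_high`
#' times lognormal multiplicative noise of coefficient of variation `cv`
#' (mean-preserving parameterization); below threshold, zero with
#' probability `zero_fraction`, otherwise a small lognormal background.
#'
#' @param object a `two_state` model.
#' @param nsim number of replicate simulations.
#' @param seed RNG seed (restores the caller's RNG state).
#' @param temperature temperatures to simulate at; defaults to training data.
#' @param cv coefficient of variation of viable-state noise (default 0.1).
#' @param zero_fraction probability a below-threshold record is exactly zero
#'   (default 1).
#' @param low_median median of the nonzero below-threshold background
#'   (default 10 cells/mL).
#' @param ... unused.
#' @return data frame with `temperature_C` and one `sim_k` column per
#'   replicate.
#' @export
simulate.two_state <- function(object, nsim = 1, seed = NULL,
                               temperature = NULL, cv = 0.1,
                               zero_fraction = 1, low_median = 10, ...) {
  temp <- if (!is.null(temperature)) temperature
  else if (!is.null(object$data)) object$data$temperature_C
  else stop("supply 'temperature'")
  draw <- function() {
    above <- temp >= object$t_threshold
    out <- numeric(length(temp))
    if (any(above)) {
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        out[above] <- stats::rlnorm(sum(above),
                                    meanlog = log(object$c_high) - sdlog^2 / 2,
                                    sdlog = sdlog)
      } else out[above] <- object$c_high
    }
    if (any(!above) && zero_fraction < 1) {
      nb <- sum(!above)
      nz <- stats::runif(nb) >= zero_fraction
      bg <- numeric(nb)
      bg[nz] <- stats::rlnorm(sum(nz), meanlog = log(low_median), sdlog = 1)
      out[!above] <- bg
    }
    out
  }
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(seed, replicate(nsim, draw()))
  sims <- matrix(sims, ncol = nsim)
  colnames(sims) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(temperature_C = temp), as.data.frame(sims))
}

#' Plot a two-state fit
#'
#' Observed abundance against temperature (log10 scale with the zero
#' convention) with the fitted step function overlaid.
#'
#' @param x a fitted `two_state` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.two_state <- function(x, ...) {
  if (is.null(x$data)) stop("model carries no training data to plot")
  temp <- x$data$temperature_C
  la <- log10_clip(x$data$abundance_cells_per_ml)
  graphics::plot(temp, la, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "temperature (degC)",
                 ylab = "log10 abundance (cells/mL, zeros -> 0)", ...)
  tg <- seq(min(temp), max(temp), length.out = 400)
  graphics::lines(tg, log10_clip(predict(x, temperature = tg)),
                  col = "firebrick", lwd = 2)
  graphics::abline(v = x$t_threshold, lty = 3)
  invisible(x)
}
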