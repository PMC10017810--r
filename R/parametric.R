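# Pluggable parametric SDM interface. The original temperature+PAR
# regression for Prochlorococcus is monotone increasing in temperature and
# in PAR up to a saturation value; its coefficients are supplied by the
# user (they are configuration, not package constants).

sdm_forms <- list(
  # constant abundance everywhere
  constant = function(coef) {
    if (!"value" %in% names(coef)) stop("form 'constant' needs coefficient 'value'")
    function(temperature, par) rep_len(coef[["value"]], max(length(temperature), length(par)))
  },
  # step function in temperature (the two-state model through this interface)
  two_state = function(coef) {
    need <- c("t_threshold", "c_high")
    if (!all(need %in% names(coef)))
      stop("form 'two_state' needs coefficients: ", paste(need, collapse = ", "))
    function(temperature, par)
      ifelse(temperature >= coef[["t_threshold"]], coef[["c_high"]], 0)
  },
  # log10 abundance linear in T and in PAR saturating at par_break:
  # log10(C) = b0 + b_T * T + b_par * min(par, par_break)
  loglinear_saturating = function(coef) {
    need <- c("b0", "b_T", "b_par", "par_break")
    if (!all(need %in% names(coef)))
      stop("form 'loglinear_saturating' needs coefficients: ", paste(need, collapse = ", "))
    function(temperature, par)
      10^(coef[["b0"]] + coef[["b_T"]] * temperature +
            coef[["b_par"]] * pmin(par, coef[["par_break"]]))
  }
)

#' Construct a parametric SDM from a coefficient set
#'
#' Wraps a named functional form and user-supplied coefficients into a
#' predictor of abundance from temperature and PAR, with declared valid
#' input ranges. Available forms: `"constant"`, `"two_state"`, and
#' `"loglinear_saturating"` (log10 abundance linear in temperature and in
#' PAR up to a saturation value `par_break`).
#'
#' @param form functional-form identifier.
#' @param coefficients named numeric vector or list of coefficients for the
#'   form.
#' @param t_range,par_range declared valid input ranges (length-2 numeric).
#' @return an object of class `parametric_sdm`.
#' @export
parametric_sdm <- function(form, coefficients = numeric(),
                           t_range = c(-2, 35), par_range = c(0, 70)) {
  if (!form %in% names(sdm_forms))
    stop("unknown functional form '", form, "'; available: ",
         paste(names(sdm_forms), collapse = ", "))
  coefficients <- as.list(coefficients)
  fn <- sdm_forms[[form]](coefficients)
  structure(list(form = form, coefficients = coefficients, fn = fn,
                 t_range = sort(t_range), par_range = sort(par_range)),
            class = "parametric_sdm")
}

#' Predict abundance from a parametric SDM
#'
#' @param object a [parametric_sdm()].
#' @param temperature temperatures in deg C.
#' @param par PAR values (same units the coefficients were fitted in).
#' @param extrapolate allow inputs outside the declared ranges
#'   (default `FALSE`, which errors on out-of-range input).
#' @param ... unused.
#' @return non-negative abundances in cells/mL.
#' @export
predict.parametric_sdm <- function(object, temperature, par,
                                   extrapolate = FALSE, ...) {
  if (!extrapolate) {
    if (any(temperature < object$t_range[1] | temperature > object$t_range[2]))
      stop("temperature outside declared range [", object$t_range[1], ", ",
           object$t_range[2], "]; set extrapolate = TRUE to override")
    if (any(par < object$par_range[1] | par > object$par_range[2]))
      stop("par outside declared range [", object$par_range[1], ", ",
           object$par_range[2], "]; set extrapolate = TRUE to override")
  }
  out <- object$fn(temperature, par)
  if (any(!is.finite(out))) stop("prediction is not finite over these inputs")
  pmax(out, 0)
}

#' @export
print.parametric_sdm <- function(x, ...) {
  cat("Parametric SDM, form '", x$form, "'\n", sep = "")
  if (length(x$coefficients))
    cat("  coefficients:", paste(names(x$coefficients),
                                 unlist(x$coefficients), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  valid ranges: T in [%g, %g] degC, PAR in [%g, %g]\n",
              x$t_range[1], x$t_range[2], x$par_range[1], x$par_range[2]))
  invisible(x)
}

#' Validate qualitative monotonicity of a parametric SDM
#'
#' Checks, on a grid over the declared ranges, that predictions are
#' monotone non-decreasing in temperature at every PAR value, and monotone
#' non-decreasing in PAR below `par_break` (where the form declares one) at
#' every temperature — the qualitative behaviour expected of a
#' temperature/light niche regression for this organism.
#'
#' @param sdm a [parametric_sdm()].
#' @param n_grid grid points per axis (default 25).
#' @return list with `ok` (logical) and `violations` (data frame of grid
#'   points where monotonicity fails; empty when `ok`).
#' @export
validate_monotone <- function(sdm, n_grid = 25) {
  stopifnot(inherits(sdm, "parametric_sdm"))
  tg <- seq(sdm$t_range[1], sdm$t_range[2], length.out = n_grid)
  pb <- sdm$coefficients[["par_break"]]
  par_hi <- if (!is.null(pb)) min(pb, sdm$par_range[2]) else sdm$par_range[2]
  pg <- seq(sdm$par_range[1], par_hi, length.out = n_grid)
  viol <- list()
  tol <- 1e-9
  for (p in pg) {
    pred <- predict(sdm, tg, rep(p, n_grid))
    bad <- which(diff(pred) < -tol)
    if (length(bad))
      viol[[length(viol) + 1]] <- data.frame(axis = "temperature",
                                             temperature = tg[bad], par = p)
  }
  for (t in tg) {
    pred <- predict(sdm, rep(t, n_grid), pg)
    bad <- which(diff(pred) < -tol)
    if (length(bad))
      viol[[length(viol) + 1]] <- data.frame(axis = "par",
                                             temperature = t, par = pg[bad])
  }
  viol <- if (length(viol)) do.call(rbind, viol)
  else data.frame(axis = character(), temperature = numeric(), par = numeric())
  list(ok = nrow(viol) == 0, violations = viol)
}
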