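#' Relative equivalent potency
#'
#' ReP of a test compound against the reference toxicant on a shared
#' endpoint: EC50(reference) / EC50(test). A censored EC50 on either side
#' (threshold reported as "> max tested") makes the ReP undefined (NA).
#'
#' @param ec50_reference reference-compound EC50 (ug/L), > 0.
#' @param ec50_test test-compound EC50 (ug/L), > 0.
#' @param censored logical: either input censored? Default FALSE.
#' @return dimensionless potency ratio (full precision; round at display).
#' @export
relative_potency <- function(ec50_reference, ec50_test, censored = FALSE) {
  if (censored) return(NA_real_)
  if (!is.finite(ec50_reference) || !is.finite(ec50_test) ||
      ec50_reference <= 0 || ec50_test <= 0) {
    return(NA_real_)
  }
  ec50_reference / ec50_test
}

#' Growth-to-yield EC50 sensitivity ratio
#'
#' Ratio of the growth-endpoint EC50 to the quantum-yield EC50 for the same
#' compound. Values above 1 mean the photophysiological endpoint responds at
#' lower concentrations than growth. Censored inputs give NA.
#'
#' @param ec50_sgr EC50 for specific growth rate inhibition (ug/L).
#' @param ec50_yield EC50 for effective-quantum-yield inhibition (ug/L).
#' @param censored logical: either input censored? Default FALSE.
#' @return dimensionless ratio.
#' @export
endpoint_ratio <- function(ec50_sgr, ec50_yield, censored = FALSE) {
  if (censored) return(NA_real_)
  if (!is.finite(ec50_sgr) || !is.finite(ec50_yield) ||
      ec50_sgr <= 0 || ec50_yield <= 0) {
    return(NA_real_)
  }
  ec50_sgr / ec50_yield
}

#' Endpoint-sensitivity regression: yield inhibition vs growth inhibition
#'
#' Ordinary least squares of per-treatment mean quantum-yield inhibition
#' (response) on mean growth-rate inhibition (predictor), with intercept.
#' A slope above 1 indicates the yield endpoint responds more steeply than
#' growth across the tested concentrations.
#'
#' @param sgr_inhibition per-treatment mean SGR inhibition (%), predictor.
#' @param yield_inhibition per-treatment mean yield inhibition (%), response;
#'   same length, n >= 3.
#' @return list of class \code{sensitivity_regression}: \code{slope},
#'   \code{slope_ci} (95%), \code{intercept}, \code{r_squared}, \code{n},
#'   \code{model} (the underlying \code{lm}).
#' @export
sensitivity_regression <- function(sgr_inhibition, yield_inhibition) {
  stopifnot(length(sgr_inhibition) == length(yield_inhibition))
  keep <- is.finite(sgr_inhibition) & is.finite(yield_inhibition)
  x <- sgr_inhibition[keep]
  y <- yield_inhibition[keep]
  if (length(x) < 3) stop("regression needs >= 3 paired points", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("zero variance in growth inhibition; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ci <- if (length(x) > 2) stats::confint(fit, "x", level = 0.95)
        else matrix(NA_real_, 1, 2)
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    slope_ci = unname(ci[1, ]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = summary(fit)$r.squared,
    n = length(x),
    model = fit
  ), class = "sensitivity_regression")
}

#' @export
print.sensitivity_regression <- function(x, ...) {
  cat(sprintf("Yield-vs-growth inhibition regression: slope %.3g", x$slope))
  if (all(is.finite(x$slope_ci))) {
    cat(sprintf(" (95%% CI %.3g-%.3g)", x$slope_ci[1], x$slope_ci[2]))
  }
  cat(sprintf(", R-squared %.3f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Potency summary for one compound against a reference
#'
#' Bundles the relative potencies on both endpoints and the growth:yield
#' EC50 ratio. The reference compound against itself has ReP exactly 1.
#'
#' @param ec50_sgr,ec50_yield test-compound EC50s (ug/L); pass the
#'   \code{ec_estimate} objects from a fit or plain numbers.
#' @param ref_ec50_sgr,ref_ec50_yield reference-compound EC50s (ug/L).
#' @param reference_name label of the reference compound.
#' @return list of class \code{potency_summary}.
#' @export
potency_summary <- function(ec50_sgr, ec50_yield = NULL,
                            ref_ec50_sgr = NULL, ref_ec50_yield = NULL,
                            reference_name = "reference") {
  val <- function(e) if (inherits(e, "ec_estimate")) e$value else e
  cens <- function(e) if (inherits(e, "ec_estimate")) isTRUE(e$censored) else FALSE
  structure(list(
    rep_sgr = if (!is.null(ref_ec50_sgr)) {
      relative_potency(val(ref_ec50_sgr), val(ec50_sgr),
                       censored = cens(ref_ec50_sgr) || cens(ec50_sgr))
    } else NA_real_,
    rep_yield = if (!is.null(ref_ec50_yield) && !is.null(ec50_yield)) {
      relative_potency(val(ref_ec50_yield), val(ec50_yield),
                       censored = cens(ref_ec50_yield) || cens(ec50_yield))
    } else NA_real_,
    ec50_ratio = if (!is.null(ec50_yield)) {
      endpoint_ratio(val(ec50_sgr), val(ec50_yield),
                     censored = cens(ec50_sgr) || cens(ec50_yield))
    } else NA_real_,
    reference_name = reference_name
  ), class = "potency_summary")
}

#' @export
print.potency_summary <- function(x, ...) {
  cat("Potency summary (reference:", x$reference_name, ")\n")
  cat(sprintf("  ReP (growth): %s\n", format_sigfig(x$rep_sgr)))
  cat(sprintf("  ReP (yield):  %s\n", format_sigfig(x$rep_yield)))
  cat(sprintf("  EC50 growth : yield ratio: %s\n",
              format_sigfig(x$ec50_ratio)))
  invisible(x)
}
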