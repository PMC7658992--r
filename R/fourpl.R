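#' Four-parameter logistic response function
#'
#' Mean percent inhibition at concentration \code{conc} under the 4PL
#' (sigmoidal, four-parameter) model used for ECx derivation:
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} EC50 - \log_{10} c)\,hill}}}
#' For \code{hill > 0} the curve is nondecreasing in concentration, running
#' from \code{bottom} at low concentration to \code{top} at high.
#'
#' @param conc concentration (ug/L), positive; vectorised.
#' @param bottom,top lower/upper asymptote (percent inhibition).
#' @param hill slope parameter (dimensionless, > 0 for inhibition curves).
#' @param log_ec50 log10 of the midpoint concentration.
#' @return mean percent inhibition.
#' @export
fourpl_response <- function(conc, bottom, top, hill, log_ec50) {
  stopifnot(all(conc > 0))
  bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(conc)) * hill))
}

#' @keywords internal
#' @noRd
fourpl_bounds <- function(log_range) {
  list(lower = c(bottom = -30, top = 40, hill = 1e-3,
                 log_ec50 = log_range[1] - 1),
       upper = c(bottom = 40, top = 120, hill = 10,
                 log_ec50 = log_range[2] + 1))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of percent inhibition against log10 concentration by
#' Levenberg-Marquardt with box constraints, restarted from 8 deterministic
#' starting points (combinations of midpoint and slope guesses) and keeping
#' the best converged fit. Controls (concentration 0) are not placed on the
#' log axis: they define the 0% inhibition baseline upstream and any zero
#' concentrations passed in are dropped with a warning.
#'
#' @param conc concentrations (ug/L), replicate-level (repeats allowed);
#'   at least 4 distinct positive values are required.
#' @param inhibition percent inhibition per replicate, same length.
#' @param ec_levels ECx levels (percent) computed on the fitted curve
#'   (default 10 and 50).
#' @return object of class \code{fourpl_fit} with components
#'   \code{coefficients} (bottom, top, hill, log_ec50), \code{r_squared},
#'   \code{ec_estimates} (list of [ec_x()] results), \code{converged},
#'   \code{n_points}, \code{max_tested}, \code{data}.
#' @seealso [ec_x()], [bootstrap_ci()], [fourpl_response()]
#' @export
fit_4pl <- function(conc, inhibition, ec_levels = c(10, 50)) {
  stopifnot(length(conc) == length(inhibition))
  keep <- is.finite(conc) & is.finite(inhibition)
  conc <- conc[keep]; inhibition <- inhibition[keep]
  if (any(conc <= 0)) {
    warning("dropping ", sum(conc <= 0),
            " record(s) at concentration <= 0 (baseline only)")
    inhibition <- inhibition[conc > 0]
    conc <- conc[conc > 0]
  }
  if (length(unique(conc)) < 4) {
    stop("at least 4 distinct positive concentrations are required",
         call. = FALSE)
  }
  lx <- log10(conc)
  log_range <- range(lx)
  bd <- fourpl_bounds(log_range)
  df <- data.frame(lx = lx, y = inhibition)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  b0 <- clamp(min(inhibition), bd$lower["bottom"], bd$upper["bottom"])
  t0 <- clamp(max(inhibition), bd$lower["top"], bd$upper["top"])
  mids <- seq(log_range[1], log_range[2], length.out = 4)
  starts <- expand.grid(log_ec50 = mids, hill = c(0.5, 2),
                        KEEP.OUT.ATTRS = FALSE)

  best <- NULL
  best_sse <- Inf
  for (k in seq_len(nrow(starts))) {
    st <- list(bottom = unname(b0), top = unname(t0),
               hill = starts$hill[k], log_ec50 = starts$log_ec50[k])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((log_ec50 - lx) * hill)),
        data = df, start = st, lower = bd$lower, upper = bd$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from all starting points", call. = FALSE)
  }
  cf <- stats::coef(best)[c("bottom", "top", "hill", "log_ec50")]
  sst <- sum((inhibition - mean(inhibition))^2)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_

  obj <- structure(list(
    coefficients = cf,
    r_squared = r2,
    sse = best_sse,
    sigma = sqrt(best_sse / max(length(conc) - 4, 1)),
    converged = TRUE,
    n_points = length(conc),
    max_tested = max(conc),
    data = data.frame(conc = conc, inhibition = inhibition),
    ec_estimates = list()
  ), class = "fourpl_fit")
  obj$ec_estimates <- stats::setNames(
    lapply(ec_levels, function(lv) ec_x(obj, lv)),
    paste0("EC", ec_levels))
  obj
}

#' Effect concentration at a given inhibition level
#'
#' Inverts the fitted 4PL mean curve at an absolute inhibition level
#' (percent of the control response, control = 0%):
#' \deqn{EC_x = 10^{\log_{10} EC50 - \log_{10}((top - x)/(x - bottom))/hill}}
#' When the level lies outside the open interval between the asymptotes, or
#' the solution exceeds the highest tested concentration, the estimate is
#' censored and reported as greater than the maximum tested concentration.
#'
#' @param fit a converged [fit_4pl()] object.
#' @param level inhibition level in percent (e.g. 10 or 50).
#' @return list of class \code{ec_estimate}: \code{level}, \code{value}
#'   (ug/L), \code{ci_low}/\code{ci_high} (NA until [bootstrap_ci()] fills
#'   them), \code{censored}.
#' @export
ec_x <- function(fit, level) {
  stopifnot(inherits(fit, "fourpl_fit"), fit$converged)
  cf <- fit$coefficients
  lo <- min(cf["bottom"], cf["top"])
  hi <- max(cf["bottom"], cf["top"])
  censor <- function() {
    structure(list(level = level, value = fit$max_tested,
                   ci_low = NA_real_, ci_high = NA_real_, censored = TRUE),
              class = "ec_estimate")
  }
  if (level <= lo || level >= hi) return(censor())
  ratio <- (cf[["top"]] - level) / (level - cf[["bottom"]])
  value <- 10^(cf[["log_ec50"]] - log10(ratio) / cf[["hill"]])
  if (value > fit$max_tested) return(censor())
  structure(list(level = level, value = unname(value),
                 ci_low = NA_real_, ci_high = NA_real_, censored = FALSE),
            class = "ec_estimate")
}

#' Bootstrap confidence interval for an ECx estimate
#'
#' Nonparametric case bootstrap: replicates are resampled with replacement
#' within each concentration group, the 4PL is refitted (starting from the
#' full-data estimates), and the percentile 2.5/97.5 interval of the ECx
#' distribution is returned. Deterministic given \code{seed}. Resamples whose
#' fit fails or whose ECx is censored are dropped; if more than 20% drop out
#' a wide-interval warning is attached to the result.
#'
#' @param conc,inhibition replicate-level data as in [fit_4pl()].
#' @param level ECx level in percent.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list of class \code{ec_estimate} with \code{ci_low},
#'   \code{ci_high} filled, plus \code{n_boot}, \code{n_failed} and
#'   \code{warning} (NULL or a message).
#' @export
bootstrap_ci <- function(conc, inhibition, level = 50, n_boot = 2000, seed = 1) {
  keep <- is.finite(conc) & is.finite(inhibition) & conc > 0
  conc <- conc[keep]; inhibition <- inhibition[keep]
  full <- fit_4pl(conc, inhibition, ec_levels = level)
  point <- full$ec_estimates[[1]]
  start <- as.list(full$coefficients)
  bd <- fourpl_bounds(range(log10(conc)))
  groups <- split(seq_along(conc), conc)
  lx_all <- log10(conc)

  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      df <- data.frame(lx = lx_all[idx], y = inhibition[idx])
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^((log_ec50 - lx) * hill)),
          data = df, start = start, lower = bd$lower, upper = bd$upper,
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      cf <- stats::coef(fit)
      lo <- min(cf["bottom"], cf["top"]); hi <- max(cf["bottom"], cf["top"])
      if (level <= lo || level >= hi) return(NA_real_)
      ratio <- (cf[["top"]] - level) / (level - cf[["bottom"]])
      10^(cf[["log_ec50"]] - log10(ratio) / cf[["hill"]])
    }, numeric(1))
  })
  ok <- is.finite(draws)
  n_failed <- sum(!ok)
  warn <- NULL
  if (n_failed > 0.2 * n_boot) {
    warn <- sprintf("%d/%d bootstrap refits failed; interval may be wide",
                    n_failed, n_boot)
    warning(warn, call. = FALSE)
  }
  qs <- stats::quantile(draws[ok], c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(level = level, value = point$value,
                 ci_low = qs[1], ci_high = qs[2],
                 censored = point$censored,
                 n_boot = n_boot, n_failed = n_failed, warning = warn),
            class = "ec_estimate")
}

#' One-way ANOVA across treatments for a nonresponsive assay
#'
#' Classical fixed-effects one-way ANOVA on the raw endpoint values by
#' treatment (reference-toxicant treatments are excluded), used to test for
#' any concentration effect when no concentration-response relationship is
#' apparent. Degenerate inputs with zero within-group variance return exact
#' p-values (0 when group means differ, 1 otherwise) with a note.
#'
#' @param tbl an [endpoint_table()].
#' @param endpoint \code{"sgr"} or \code{"yield"}.
#' @return list of class \code{anova_result}: \code{f_statistic},
#'   \code{df_between}, \code{df_within}, \code{p_value}, \code{note}.
#' @export
nonresponse_anova <- function(tbl, endpoint = c("sgr", "yield")) {
  stopifnot(inherits(tbl, "endpoint_table"))
  endpoint <- match.arg(endpoint)
  reps <- tbl$replicates[tbl$replicates$role != "reference", , drop = FALSE]
  y <- reps[[endpoint]]
  keep <- !is.na(y)
  y <- y[keep]
  g <- factor(reps$treatment[keep])
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("ANOVA needs >= 2 treatments with >= 2 replicates each",
         call. = FALSE)
  }
  df_b <- length(counts) - 1L
  df_w <- length(y) - length(counts)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  note <- NULL
  if (ssw == 0) {
    means <- tapply(y, g, mean)
    sep <- max(means) - min(means) > 0
    note <- "zero within-group variance: exact separation"
    res <- list(f_statistic = if (sep) Inf else 0,
                df_between = df_b, df_within = df_w,
                p_value = if (sep) 0 else 1, note = note)
    return(structure(res, class = "anova_result"))
  }
  av <- stats::anova(stats::aov(y ~ g))
  structure(list(f_statistic = av[["F value"]][1],
                 df_between = av[["Df"]][1],
                 df_within = av[["Df"]][2],
                 p_value = av[["Pr(>F)"]][1],
                 note = note),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Classify an assay as responsive or nonresponsive
#'
#' An assay is declared nonresponsive when the one-way ANOVA across
#' treatments is not significant (p >= 0.05) AND the mean inhibition at the
#' highest tested concentration stays below 10%. Nonresponsive assays are
#' routed to censored threshold reporting ("> max tested") for EC10, EC50
#' and NEC.
#'
#' @param tbl an [endpoint_table()] covering >= 4 concentrations.
#' @param endpoint \code{"sgr"} or \code{"yield"}.
#' @param alpha ANOVA significance cutoff (default 0.05).
#' @param max_top_inhibition top-concentration mean inhibition cutoff in
#'   percent (default 10).
#' @return list of class \code{response_class}: \code{responsive} (flag),
#'   \code{p_value}, \code{top_inhibition}, \code{max_conc}, \code{anova}.
#' @export
classify_response <- function(tbl, endpoint = c("sgr", "yield"),
                              alpha = 0.05, max_top_inhibition = 10) {
  stopifnot(inherits(tbl, "endpoint_table"))
  endpoint <- match.arg(endpoint)
  tr <- tbl$treatments[tbl$treatments$role == "test", , drop = FALSE]
  if (length(unique(tr$twa_conc)) < 4) {
    stop("classification needs >= 4 test concentrations", call. = FALSE)
  }
  av <- nonresponse_anova(tbl, endpoint)
  top_tr <- tr$treatment[which.max(tr$twa_conc)]
  inh_col <- paste0(endpoint, "_inhibition")
  reps <- tbl$replicates
  top_inh <- mean(reps[[inh_col]][reps$treatment == top_tr], na.rm = TRUE)
  nonresp <- (av$p_value >= alpha) && (top_inh < max_top_inhibition)
  structure(list(responsive = !nonresp, p_value = av$p_value,
                 top_inhibition = top_inh, max_conc = max(tr$twa_conc),
                 anova = av),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("Assay classified %s (ANOVA p = %.3g, top-concentration inhibition %.1f%%)\n",
              if (x$responsive) "RESPONSIVE" else "NONRESPONSIVE",
              x$p_value, x$top_inhibition))
  invisible(x)
}

# ---- fourpl_fit methods ------------------------------------------------

#' @export
coef.fourpl_fit <- function(object, ...) object$coefficients

#' @export
fitted.fourpl_fit <- function(object, ...) {
  cf <- object$coefficients
  fourpl_response(object$data$conc, cf["bottom"], cf["top"], cf["hill"],
                  cf["log_ec50"])
}

#' @export
residuals.fourpl_fit <- function(object, ...) {
  object$data$inhibition - fitted(object)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$conc
  } else if (is.data.frame(newdata)) {
    newdata$conc
  } else {
    newdata
  }
  cf <- object$coefficients
  fourpl_response(conc, cf["bottom"], cf["top"], cf["hill"], cf["log_ec50"])
}

#' @export
simulate.fourpl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  gen <- function() mu + stats::rnorm(length(mu), 0, object$sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, gen(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  }
  as.data.frame(stats::setNames(sims, paste0("sim_", seq_len(nsim))))
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic concentration-response fit\n")
  cat(sprintf("  bottom %.3g  top %.3g  hill %.3g  EC50 %.4g ug/L\n",
              cf["bottom"], cf["top"], cf["hill"], 10^cf["log_ec50"]))
  cat(sprintf("  R-squared %.4f on %d replicate points\n",
              x$r_squared, x$n_points))
  for (nm in names(x$ec_estimates)) {
    e <- x$ec_estimates[[nm]]
    cat(sprintf("  %s: %s ug/L\n", nm,
                format_threshold(e$value, e$censored)))
  }
  invisible(x)
}

#' @export
summary.fourpl_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fourpl_fit")
}

#' @export
print.summary.fourpl_fit <- function(x, ...) {
  print(x$fit)
  r <- residuals(x$fit)
  cat(sprintf("  residual sd %.3g, range [%.3g, %.3g]\n",
              stats::sd(r), min(r), max(r)))
  invisible(x)
}

#' @export
print.ec_estimate <- function(x, ...) {
  cat(sprintf("EC%g = %s ug/L", x$level, format_threshold(x$value, x$censored)))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %s-%s)", format_sigfig(x$ci_low),
                format_sigfig(x$ci_high)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  d <- x$data
  cf <- x$coefficients
  grid <- 10^seq(log10(min(d$conc)) - 0.3, log10(max(d$conc)) + 0.3,
                 length.out = 200)
  graphics::plot(d$conc, d$inhibition, log = "x",
                 xlab = "concentration (ug/L)", ylab = "inhibition (%)", ...)
  graphics::lines(grid, fourpl_response(grid, cf["bottom"], cf["top"],
                                        cf["hill"], cf["log_ec50"]))
  invisible(x)
}
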