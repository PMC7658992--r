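#' Mean function of the NEC threshold model
#'
#' Piecewise-exponential threshold ("broken-stick") mean used for no-effect
#' concentration estimation on proportional responses:
#' \deqn{\mu(x) = \alpha \exp[-\beta (x - \gamma) I(x - \gamma)] - \Delta}
#' where \eqn{I(z) = 1} for \eqn{z > 0} and 0 otherwise. The mean is constant
#' at \eqn{\alpha - \Delta} for \eqn{x \le \gamma} (no effect below the
#' threshold), decays exponentially above it, and is continuous at
#' \eqn{x = \gamma}; for \eqn{\beta \ge 0} it is non-increasing in x.
#'
#' @param x log concentration (natural log of ug/L); vectorised.
#' @param alpha response at and below the threshold ("top"), response units.
#' @param beta decay rate per unit log concentration (>= 0).
#' @param gamma threshold: the NEC on the natural-log concentration scale.
#' @param delta offset (response units).
#' @return expected response at each x.
#' @export
nec_model_mean <- function(x, alpha, beta, gamma, delta = 0) {
  alpha * exp(-beta * pmax(x - gamma, 0)) - delta
}

#' Gaussian log-likelihood of the NEC model
#'
#' Sum of normal log-densities of the responses about [nec_model_mean()],
#' the likelihood targeted by the MCMC sampler in [fit_nec()].
#'
#' @param params named numeric vector or list with \code{alpha},
#'   \code{beta}, \code{gamma}, \code{delta}, \code{sigma}.
#' @param data a \code{nec_data} object from [nec_design_matrix()] or any
#'   list with numeric \code{x} and \code{y}.
#' @return scalar log-likelihood.
#' @export
nec_loglik <- function(params, data) {
  p <- as.list(params)
  if (p$sigma <= 0) return(-Inf)
  mu <- nec_model_mean(data$x, p$alpha, p$beta, p$gamma, p$delta)
  sum(stats::dnorm(data$y, mu, p$sigma, log = TRUE))
}

#' Design data for NEC fitting
#'
#' Builds the (x, y) pairs the threshold model is fitted to: per replicate,
#' y is the proportional response (1 - inhibition/100, so controls sit near
#' 1) and x the natural log of the treatment's time-weighted average
#' concentration. Control replicates have no finite log concentration and
#' are placed a fixed number of decades below the lowest test treatment;
#' the placement is recorded in \code{control_x_policy}. Reference-toxicant
#' treatments are excluded.
#'
#' @param tbl an [endpoint_table()].
#' @param endpoint \code{"sgr"} (default) or \code{"yield"}.
#' @param control_decades decades below the lowest treatment concentration
#'   at which control replicates are placed (default 1; 0.5 and 2 are
#'   offered for sensitivity analysis).
#' @return object of class \code{nec_data}: \code{x}, \code{y},
#'   \code{is_control}, \code{max_conc} (ug/L), \code{control_x_policy},
#'   \code{herbicide}, \code{endpoint}.
#' @export
nec_design_matrix <- function(tbl, endpoint = c("sgr", "yield"),
                              control_decades = 1) {
  stopifnot(inherits(tbl, "endpoint_table"))
  endpoint <- match.arg(endpoint)
  inh_col <- paste0(endpoint, "_inhibition")
  reps <- tbl$replicates[tbl$replicates$role != "reference", , drop = FALSE]
  reps <- merge(reps, tbl$treatments[c("treatment", "twa_conc")],
                by = "treatment", sort = FALSE)
  reps <- reps[!is.na(reps[[inh_col]]), , drop = FALSE]
  is_ctrl <- reps$role %in% c("control", "solvent_control")
  test_conc <- reps$twa_conc[!is_ctrl]
  if (!length(test_conc) || any(test_conc <= 0)) {
    stop("NEC design needs positive exposure concentrations for all test treatments",
         call. = FALSE)
  }
  control_conc <- min(test_conc) / 10^control_decades
  x <- ifelse(is_ctrl, log(control_conc), log(reps$twa_conc))
  y <- 1 - reps[[inh_col]] / 100
  structure(list(
    x = x, y = y, is_control = is_ctrl,
    max_conc = max(test_conc),
    control_x_policy = sprintf(
      "controls placed at ln(%.6g ug/L) = lowest treatment / 10^%g",
      control_conc, control_decades),
    herbicide = tbl$herbicide, endpoint = endpoint
  ), class = "nec_data")
}

#' Prior specification for the NEC model
#'
#' Weakly informative defaults, each overridable: the threshold gamma is
#' uniform over the observed log-concentration range (extended 0.5 below);
#' alpha is a positive-truncated normal centred on the mean control
#' response with sd = 10 x the control-response sd (floored at 0.25); beta
#' has a vague Gamma(1e-4, 1e-4) prior; delta a Normal(0, 1); sigma a
#' half-Cauchy with scale 1.
#'
#' @param data a \code{nec_data} object used to fill data-dependent
#'   defaults; may be NULL if all arguments are supplied.
#' @param alpha_mean,alpha_sd,beta_shape,beta_rate,delta_mean,delta_sd,sigma_scale,gamma_lower,gamma_upper
#'   overrides for individual hyperparameters.
#' @return list of class \code{nec_priors}.
#' @export
nec_priors <- function(data = NULL, alpha_mean = NULL, alpha_sd = NULL,
                       beta_shape = 1e-4, beta_rate = 1e-4,
                       delta_mean = 0, delta_sd = 1, sigma_scale = 1,
                       gamma_lower = NULL, gamma_upper = NULL) {
  if (is.null(alpha_mean) || is.null(alpha_sd) ||
      is.null(gamma_lower) || is.null(gamma_upper)) {
    stopifnot(!is.null(data))
    ctrl_y <- if (any(data$is_control)) data$y[data$is_control] else data$y
    if (is.null(alpha_mean)) alpha_mean <- mean(ctrl_y)
    if (is.null(alpha_sd)) {
      s <- stats::sd(ctrl_y)
      alpha_sd <- max(10 * ifelse(is.finite(s), s, 0), 0.25)
    }
    if (is.null(gamma_lower)) gamma_lower <- min(data$x) - 0.5
    if (is.null(gamma_upper)) gamma_upper <- max(data$x)
  }
  structure(list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_shape = beta_shape, beta_rate = beta_rate,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 sigma_scale = sigma_scale,
                 gamma_lower = gamma_lower, gamma_upper = gamma_upper),
            class = "nec_priors")
}

#' @keywords internal
#' @noRd
nec_logprior <- function(theta, pr) {
  alpha <- theta[1]; beta <- theta[2]; gamma <- theta[3]
  delta <- theta[4]; sigma <- theta[5]
  if (alpha <= 0 || beta < 0 || sigma <= 0 ||
      gamma < pr$gamma_lower || gamma > pr$gamma_upper) {
    return(-Inf)
  }
  # truncated-normal alpha: truncation constant does not depend on alpha
  lp <- stats::dnorm(alpha, pr$alpha_mean, pr$alpha_sd, log = TRUE)
  lp <- lp + stats::dgamma(beta, shape = pr$beta_shape, rate = pr$beta_rate,
                           log = TRUE)
  lp <- lp + stats::dnorm(delta, pr$delta_mean, pr$delta_sd, log = TRUE)
  lp <- lp - log(1 + (sigma / pr$sigma_scale)^2)  # half-Cauchy kernel
  lp  # gamma uniform: constant inside bounds
}

#' Fit the Bayesian no-effect-concentration model
#'
#' Samples the posterior of the threshold model (see [nec_model_mean()])
#' under a gaussian likelihood with the priors of [nec_priors()], using an
#' adaptive random-walk Metropolis-within-Gibbs sampler: each parameter is
#' updated in turn with a gaussian proposal whose scale is tuned toward a
#' 44% acceptance rate during burn-in and then frozen. Runs are exactly
#' reproducible given \code{seed}. Split-chain R-hat and effective sample
#' size are computed per parameter; R-hat > 1.05 or ESS < 400 triggers a
#' non-convergence warning (the flagged result is still returned).
#'
#' @param data a \code{nec_data} object from [nec_design_matrix()].
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain including burn-in (default 10000).
#' @param burnin burn-in iterations discarded per chain (default 5000).
#' @param seed integer seed driving all chains.
#' @param priors a [nec_priors()] object; defaults are derived from
#'   \code{data}.
#' @return object of class \code{nec_fit}: \code{draws} (matrix of posterior
#'   samples of alpha, beta, gamma, delta, sigma over all chains),
#'   \code{nec_value} (posterior median of exp(gamma), ug/L), \code{nec_ci}
#'   (central 95% credible interval), \code{censored} (FALSE here; the
#'   censored path never reaches the sampler), \code{diagnostics}
#'   (per-parameter R-hat and ESS), \code{convergence_ok}, \code{seed},
#'   \code{data}, \code{priors}.
#' @export
fit_nec <- function(data, chains = 4, iter = 10000, burnin = 5000,
                    seed = 1, priors = NULL) {
  stopifnot(inherits(data, "nec_data"), iter > burnin, chains >= 1)
  if (is.null(priors)) priors <- nec_priors(data)
  pr <- priors
  x <- data$x; y <- data$y
  n <- length(y)
  par_names <- c("alpha", "beta", "gamma", "delta", "sigma")

  # The sampler walks in (top, beta, gamma, delta, sigma) with
  # top = alpha - delta (the plateau response below the threshold): alpha
  # and delta are nearly collinear in the likelihood, and this linear
  # (unit-Jacobian) reparameterisation removes the ridge. Draws are stored
  # back on the alpha scale.
  log_post <- function(theta) {
    alpha <- theta[1] + theta[4]
    lp <- nec_logprior(c(alpha, theta[2:5]), pr)
    if (!is.finite(lp)) return(-Inf)
    mu <- alpha * exp(-theta[2] * pmax(x - theta[3], 0)) - theta[4]
    lp - n * log(theta[5]) - sum((y - mu)^2) / (2 * theta[5]^2)
  }

  ctrl_y <- if (any(data$is_control)) y[data$is_control] else y
  kept <- iter - burnin
  chain_draws <- vector("list", chains)

  for (ch in seq_len(chains)) {
    chain_draws[[ch]] <- with_seed(child_seed(seed, ch), {
      # overdispersed but prior-consistent initial values (top scale)
      theta <- c(
        top = max(mean(ctrl_y) * exp(stats::runif(1, -0.2, 0.2)), 1e-3),
        beta = exp(stats::runif(1, -1.5, 1.5)),
        gamma = stats::runif(1, pr$gamma_lower, pr$gamma_upper),
        delta = stats::rnorm(1, pr$delta_mean, 0.1),
        sigma = max(stats::sd(y), 0.02) * exp(stats::runif(1, -1, 0.5))
      )
      lp <- log_post(theta)
      if (!is.finite(lp)) {  # fall back to a safe interior point
        theta <- c(mean(ctrl_y), 1, mean(c(pr$gamma_lower, pr$gamma_upper)),
                   0, max(stats::sd(y), 0.02))
        lp <- log_post(theta)
      }
      # Phase 1 (first half of burn-in): component-wise adaptive random
      # walk, robust from arbitrary starting points.
      half_burn <- max(floor(burnin / 2), 100L)
      ls <- rep(log(0.2), 5)  # log proposal sds
      acc <- integer(5)
      batch <- 0L
      ph1 <- matrix(NA_real_, half_burn, 5)
      for (it in seq_len(half_burn)) {
        z <- stats::rnorm(5)
        u <- stats::runif(5)
        for (j in 1:5) {
          prop <- theta
          prop[j] <- prop[j] + exp(ls[j]) * z[j]
          lp_prop <- log_post(prop)
          if (lp_prop - lp > log(u[j])) {
            theta <- prop
            lp <- lp_prop
            acc[j] <- acc[j] + 1L
          }
        }
        if (it %% 50L == 0L) {
          batch <- batch + 1L
          step <- min(0.1, 1 / sqrt(batch))
          ls <- ls + ifelse(acc / 50 > 0.44, step, -step)
          acc[] <- 0L
        }
        ph1[it, ] <- theta
      }
      # Phase 2: joint random walk with the empirical posterior covariance
      # (adapted until the end of burn-in, then frozen).
      emp_cov <- function(m) {
        v <- stats::cov(m)
        v + diag(pmax(diag(v), 1e-8)) * 1e-6
      }
      L <- chol(emp_cov(ph1[seq(floor(half_burn / 2), half_burn), ,
                             drop = FALSE]))
      s <- 2.38 / sqrt(5)
      accj <- 0L
      batch <- 0L
      ph2 <- matrix(NA_real_, max(burnin - half_burn, 0L), 5)
      out <- matrix(NA_real_, kept, 5)
      for (it in seq(half_burn + 1L, iter)) {
        prop <- theta + s * drop(stats::rnorm(5) %*% L)
        lp_prop <- log_post(prop)
        if (lp_prop - lp > log(stats::runif(1))) {
          theta <- prop
          lp <- lp_prop
          accj <- accj + 1L
        }
        if (it <= burnin) {
          ph2[it - half_burn, ] <- theta
          if (it %% 50L == 0L) {
            batch <- batch + 1L
            step <- min(0.1, 1 / sqrt(batch))
            s <- s * exp(if (accj / 50 > 0.23) step else -step)
            accj <- 0L
          }
          if (it == half_burn + floor((burnin - half_burn) / 2)) {
            L <- chol(emp_cov(ph2[seq_len(it - half_burn), , drop = FALSE]))
          }
          if (it == burnin) {
            # final covariance from the settled second half of burn-in
            lo <- floor((burnin - half_burn) / 2)
            L <- chol(emp_cov(ph2[seq(lo, burnin - half_burn), ,
                                  drop = FALSE]))
          }
        } else {
          out[it - burnin, ] <- theta
        }
      }
      out[, 1] <- out[, 1] + out[, 4]  # back to alpha = top + delta
      colnames(out) <- par_names
      out
    })
  }

  draws <- do.call(rbind, chain_draws)
  diag <- mcmc_diagnostics(chain_draws)
  convergence_ok <- all(diag$rhat <= 1.05) && all(diag$ess >= 400)
  if (!convergence_ok) {
    warning("NEC sampler shows incomplete convergence (max R-hat ",
            sprintf("%.3f", max(diag$rhat)), ", min ESS ",
            sprintf("%.0f", min(diag$ess)),
            "); consider longer chains", call. = FALSE)
  }
  nec_draws <- exp(draws[, "gamma"])
  qs <- stats::quantile(nec_draws, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(
    draws = draws, chain_draws = chain_draws,
    nec_value = qs[2], nec_ci = c(qs[1], qs[3]),
    censored = FALSE, max_conc = data$max_conc,
    diagnostics = diag, convergence_ok = convergence_ok,
    chains = chains, iter = iter, burnin = burnin, seed = seed,
    priors = pr, data = data
  ), class = "nec_fit")
}

# Split-chain R-hat and a Geyer-style initial-positive-sequence ESS.
#' @keywords internal
#' @noRd
mcmc_diagnostics <- function(chain_draws) {
  p <- ncol(chain_draws[[1]])
  par_names <- colnames(chain_draws[[1]])
  halves <- list()
  for (cd in chain_draws) {
    n2 <- floor(nrow(cd) / 2)
    halves <- c(halves, list(cd[seq_len(n2), , drop = FALSE],
                             cd[(n2 + 1):(2 * n2), , drop = FALSE]))
  }
  rhat <- numeric(p)
  for (j in seq_len(p)) {
    m <- length(halves)
    nn <- nrow(halves[[1]])
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- nn * stats::var(means)
    rhat[j] <- if (W > 0) sqrt(((nn - 1) / nn * W + B / nn) / W) else 1
  }
  ess <- numeric(p)
  for (j in seq_len(p)) {
    tot <- 0
    for (cd in chain_draws) {
      v <- cd[, j]
      nn <- length(v)
      if (stats::var(v) == 0) {
        tot <- tot + nn
        next
      }
      rho <- stats::acf(v, lag.max = min(nn - 1, 500), plot = FALSE,
                        demean = TRUE)$acf[, 1, 1]
      tau <- 1
      k <- 2
      while (k + 1 <= length(rho)) {
        pair <- rho[k] + rho[k + 1]
        if (pair < 0) break
        tau <- tau + 2 * pair
        k <- k + 2
      }
      tot <- tot + nn / tau
    }
    ess[j] <- tot
  }
  data.frame(parameter = par_names, rhat = rhat, ess = ess)
}

#' Posterior NEC summary
#'
#' Posterior median and central 95% credible interval of the no-effect
#' concentration exp(gamma), back on the ug/L scale. For a censored fit
#' (nonresponsive assay) the threshold is reported as greater than the
#' maximum tested concentration.
#'
#' @param fit a [fit_nec()] result or a censored NEC placeholder from
#'   [censored_nec()].
#' @return list with \code{nec_value}, \code{nec_ci}, \code{censored},
#'   \code{display} (3-significant-figure string, "> max" when censored).
#' @export
nec_summary <- function(fit) {
  stopifnot(inherits(fit, "nec_fit"))
  list(nec_value = fit$nec_value, nec_ci = fit$nec_ci,
       censored = fit$censored,
       display = format_threshold(fit$nec_value, fit$censored))
}

#' Censored NEC result for a nonresponsive assay
#'
#' Placeholder carrying the "> max tested" reporting convention through the
#' pipeline when [classify_response()] declares an assay nonresponsive and
#' no threshold model is fitted.
#'
#' @param max_conc highest tested concentration (ug/L).
#' @return a censored \code{nec_fit} stub (no posterior draws).
#' @export
censored_nec <- function(max_conc) {
  structure(list(draws = NULL, nec_value = max_conc,
                 nec_ci = c(NA_real_, NA_real_), censored = TRUE,
                 max_conc = max_conc, diagnostics = NULL,
                 convergence_ok = NA), class = "nec_fit")
}

# ---- nec_fit methods ---------------------------------------------------

#' @export
coef.nec_fit <- function(object, ...) {
  if (is.null(object$draws)) return(NULL)
  apply(object$draws, 2, stats::median)
}

#' @export
predict.nec_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$draws)) {
    stop("censored NEC fit has no posterior to predict from", call. = FALSE)
  }
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  d <- object$draws
  vapply(x, function(xi) {
    mean(d[, "alpha"] * exp(-d[, "beta"] * pmax(xi - d[, "gamma"], 0)) -
           d[, "delta"])
  }, numeric(1))
}

#' @export
print.nec_fit <- function(x, ...) {
  cat("Bayesian no-effect-concentration fit\n")
  if (x$censored) {
    cat(sprintf("  NEC > %s ug/L (nonresponsive assay, censored at the maximum tested concentration)\n",
                format_sigfig(x$max_conc)))
    return(invisible(x))
  }
  cat(sprintf("  NEC = %s ug/L (95%% CrI %s-%s)\n",
              format_sigfig(x$nec_value), format_sigfig(x$nec_ci[1]),
              format_sigfig(x$nec_ci[2])))
  cat(sprintf("  %d chains x %d iterations (%d burn-in), seed %s\n",
              x$chains, x$iter, x$burnin, format(x$seed)))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              if (isTRUE(x$convergence_ok)) "" else "  [convergence flagged]"))
  invisible(x)
}

#' @export
summary.nec_fit <- function(object, ...) {
  if (is.null(object$draws)) return(nec_summary(object))
  qtab <- t(apply(object$draws, 2, stats::quantile,
                  probs = c(0.025, 0.5, 0.975)))
  structure(list(fit = object, quantiles = qtab,
                 nec = nec_summary(object)), class = "summary.nec_fit")
}

#' @export
print.summary.nec_fit <- function(x, ...) {
  print(x$fit)
  cat("  parameter posterior quantiles (2.5/50/97.5%):\n")
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
plot.nec_fit <- function(x, ...) {
  if (is.null(x$draws)) {
    stop("censored NEC fit has nothing to plot", call. = FALSE)
  }
  d <- x$data
  grid <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::plot(d$x, d$y, xlab = "ln concentration",
                 ylab = "proportional response", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = log(x$nec_value), col = 2)
  graphics::abline(v = log(x$nec_ci), col = 2, lty = 2)
  invisible(x)
}
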