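#' Bioassay design specification
#'
#' Describes the layout of a simulated growth-inhibition assay: a seawater
#' control, an optional reference-toxicant treatment, and a series of test
#' concentrations, each with \code{n_replicates} replicate cultures started
#' at \code{start_density} and grown for \code{duration} days. Herbicide is
#' lost between 0 h and 72 h following first-order dissipation, leaving
#' \code{decay_fraction} of the nominal concentration at test end.
#'
#' @param concentrations nominal test concentrations (ug/L), strictly
#'   increasing and positive.
#' @param n_replicates replicates per treatment (default 5).
#' @param duration exposure length in days (default 3).
#' @param start_density inoculation density, cells/mL (default 3e3).
#' @param include_reference include a diuron-like reference treatment at
#'   4 ug/L (default TRUE).
#' @param decay_fraction fraction of nominal remaining at 72 h (default 0.8).
#' @return list of class \code{assay_design}.
#' @export
assay_design <- function(concentrations, n_replicates = 5, duration = 3,
                         start_density = 3e3, include_reference = TRUE,
                         decay_fraction = 0.8) {
  stopifnot(all(concentrations > 0), !is.unsorted(concentrations,
                                                  strictly = TRUE),
            n_replicates >= 2, duration > 0, start_density > 0,
            decay_fraction > 0, decay_fraction <= 1)
  structure(list(concentrations = concentrations,
                 n_replicates = n_replicates, duration = duration,
                 start_density = start_density,
                 include_reference = include_reference,
                 decay_fraction = decay_fraction),
            class = "assay_design")
}

#' Default 7-concentration assay design
#'
#' Seven geometrically spaced nominal concentrations spanning two decades
#' centred (in log space) on the truth EC50, with five replicates and a
#' reference treatment — the standard layout of the emulated assays.
#'
#' @param ec50 centre of the concentration series (ug/L, default 10).
#' @param n_conc number of test concentrations (default 7).
#' @param decades total log10 span of the series (default 2).
#' @param n_replicates replicates per treatment (default 5).
#' @param ... further arguments passed to [assay_design()].
#' @return an [assay_design()].
#' @export
default_design <- function(ec50 = 10, n_conc = 7, decades = 2,
                           n_replicates = 5, ...) {
  lg <- seq(log10(ec50) - decades / 2, log10(ec50) + decades / 2,
            length.out = n_conc)
  assay_design(10^lg, n_replicates = n_replicates, ...)
}

#' Truth model for assay simulation
#'
#' Ground-truth biology for the generator: control specific growth rate and
#' quantum yield at the magnitudes observed in healthy diatom cultures
#' (controls around 1.4-1.7 /day and 0.42-0.48 yield), a concentration-
#' inhibition curve for growth, and a sensitivity factor placing the yield
#' endpoint's EC50 a fixed factor below the growth EC50. Noise settings:
#' lognormal replicate noise on cell densities (CV-scaled, multiplicative,
#' as counting and pipetting errors are), additive gaussian noise on yields,
#' and lognormal measurement noise on chemical analyses.
#'
#' @param control_sgr control growth rate, 1/day (default 1.55).
#' @param control_yield control effective quantum yield (default 0.46).
#' @param curve growth-inhibition truth curve: either a list with
#'   \code{bottom}, \code{top}, \code{hill}, \code{ec50} (4PL, percent
#'   inhibition; the default is bottom 0, top 100, hill 1, ec50 10 ug/L) or
#'   a list with \code{alpha}, \code{beta}, \code{gamma}, \code{delta}
#'   (threshold model on the proportional-response scale).
#' @param endpoint_ratio_truth yield sensitivity factor: yield EC50 =
#'   growth EC50 / ratio (default 3).
#' @param noise_cv_density replicate CV of cell densities, percent
#'   (default 4).
#' @param noise_sd_yield additive sd of yields (default 0.01).
#' @param noise_cv_measured CV of measured concentrations, percent
#'   (default 5).
#' @param reference_inhibition_sgr,reference_inhibition_yield fixed percent
#'   inhibition of the reference treatment (defaults 23 and 42).
#' @return list of class \code{truth_model}.
#' @export
truth_model <- function(control_sgr = 1.55, control_yield = 0.46,
                        curve = list(bottom = 0, top = 100, hill = 1,
                                     ec50 = 10),
                        endpoint_ratio_truth = 3,
                        noise_cv_density = 4, noise_sd_yield = 0.01,
                        noise_cv_measured = 5,
                        reference_inhibition_sgr = 23,
                        reference_inhibition_yield = 42) {
  stopifnot(control_sgr > 0, control_yield > 0, control_yield < 1,
            endpoint_ratio_truth > 0)
  structure(list(control_sgr = control_sgr, control_yield = control_yield,
                 curve = curve, endpoint_ratio_truth = endpoint_ratio_truth,
                 noise_cv_density = noise_cv_density,
                 noise_sd_yield = noise_sd_yield,
                 noise_cv_measured = noise_cv_measured,
                 reference_inhibition_sgr = reference_inhibition_sgr,
                 reference_inhibition_yield = reference_inhibition_yield),
            class = "truth_model")
}

#' Evaluate a truth inhibition curve
#'
#' Percent inhibition at a concentration under a [truth_model()] curve,
#' optionally with the yield-endpoint EC50 shift applied.
#'
#' @param truth a [truth_model()].
#' @param conc concentration (ug/L), vectorised.
#' @param endpoint \code{"sgr"} or \code{"yield"} (applies the sensitivity
#'   shift).
#' @return percent inhibition.
#' @export
truth_inhibition <- function(truth, conc, endpoint = c("sgr", "yield")) {
  endpoint <- match.arg(endpoint)
  cv <- truth$curve
  shift <- if (endpoint == "yield") truth$endpoint_ratio_truth else 1
  if (!is.null(cv$ec50)) {
    fourpl_response(conc, cv$bottom, cv$top, cv$hill,
                    log10(cv$ec50 / shift))
  } else {
    top_resp <- cv$alpha - cv$delta
    mu <- nec_model_mean(log(conc), cv$alpha, cv$beta,
                         cv$gamma - log(shift), cv$delta)
    100 * (1 - mu / top_resp)
  }
}

# lognormal factor with unit mean and given CV (percent); CV 0 -> exactly 1
#' @keywords internal
#' @noRd
lnorm_factor <- function(n, cv_pct) {
  if (cv_pct <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a complete bioassay dataset
#'
#' Generates an [assay_dataset()] with known truth. For each test treatment
#' the measured start concentration is nominal with lognormal measurement
#' noise and the end concentration is nominal times the decay fraction
#' (again with noise); the growth inhibition truth curve is evaluated at
#' the geometric-mean (TWA) exposure of those simulated measurements, so a
#' noiseless run round-trips exactly through [endpoint_table()]. Replicate
#' growth is exponential at the inhibited rate with lognormal density noise
#' at 72 h; yields follow the shifted truth curve with additive gaussian
#' noise and are encoded as an (F, Fm') fluorescence pair with Fm' = 500.
#' Fully deterministic given \code{seed}.
#'
#' @param design an [assay_design()].
#' @param truth a [truth_model()].
#' @param seed integer seed.
#' @param herbicide dataset label (default "synthetic").
#' @return an [assay_dataset()].
#' @export
simulate_assay <- function(design, truth, seed = 1, herbicide = "synthetic") {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "truth_model"))
  with_seed(seed, {
    nrep <- design$n_replicates
    fm_const <- 500

    treatments <- data.frame(
      treatment = c("control",
                    if (design$include_reference) "reference",
                    sprintf("T%d", seq_along(design$concentrations))),
      role = c("control",
               if (design$include_reference) "reference",
               rep("test", length(design$concentrations))),
      nominal_conc = c(0, if (design$include_reference) 4,
                       design$concentrations),
      stringsAsFactors = FALSE
    )

    rows <- vector("list", nrow(treatments))
    for (k in seq_len(nrow(treatments))) {
      role <- treatments$role[k]
      nominal <- treatments$nominal_conc[k]
      if (role == "test" || role == "reference") {
        ms <- nominal * lnorm_factor(1, truth$noise_cv_measured)
        me <- nominal * design$decay_fraction *
          lnorm_factor(1, truth$noise_cv_measured)
        twa <- sqrt(ms * me)
      } else {
        ms <- NA_real_; me <- NA_real_; twa <- 0
      }
      if (role == "control") {
        inh_g <- 0; inh_y <- 0
      } else if (role == "reference") {
        inh_g <- truth$reference_inhibition_sgr
        inh_y <- truth$reference_inhibition_yield
      } else {
        inh_g <- truth_inhibition(truth, twa, "sgr")
        inh_y <- truth_inhibition(truth, twa, "yield")
      }
      rate <- truth$control_sgr * (1 - inh_g / 100)
      dens72 <- design$start_density * exp(rate * design$duration) *
        lnorm_factor(nrep, truth$noise_cv_density)
      yld <- truth$control_yield * (1 - inh_y / 100) +
        stats::rnorm(nrep, 0, truth$noise_sd_yield)
      yld <- pmin(pmax(yld, 0), 1)
      rows[[k]] <- data.frame(
        treatment = treatments$treatment[k], role = role,
        nominal_conc = nominal, replicate = sprintf("R%d", seq_len(nrep)),
        cell_density_t0 = design$start_density,
        cell_density_t72 = dens72,
        fluorescence_F = fm_const * (1 - yld),
        fluorescence_Fm = fm_const,
        measured_conc_start = ms, measured_conc_end = me,
        ph_t0 = 8.1, ph_t72 = 8.3, salinity = 35,
        dissolved_oxygen = 8.2, temperature = 27,
        stringsAsFactors = FALSE
      )
    }
    assay_dataset(herbicide, do.call(rbind, rows),
                  duration = design$duration)
  })
}

#' Simulate responses directly from the NEC threshold model
#'
#' Draws proportional responses \eqn{y \sim N(\mu(x), \sigma)} under the
#' generative form of the threshold model at each log concentration in
#' \code{x_grid}, replicated \code{n_replicates} times. The lowest grid
#' level is flagged as the control placement. Deterministic given
#' \code{seed}.
#'
#' @param params list with \code{alpha}, \code{beta}, \code{gamma},
#'   \code{delta}, \code{sigma} (sigma >= 0; 0 gives the exact mean).
#' @param x_grid log (natural) concentrations.
#' @param n_replicates replicates per grid point (default 5).
#' @param seed integer seed.
#' @return a \code{nec_data} object ready for [fit_nec()].
#' @export
simulate_from_nec <- function(params, x_grid, n_replicates = 5, seed = 1) {
  stopifnot(all(c("alpha", "beta", "gamma", "sigma") %in% names(params)),
            params$sigma >= 0)
  delta <- params$delta %||% 0
  x <- rep(x_grid, each = n_replicates)
  mu <- nec_model_mean(x, params$alpha, params$beta, params$gamma, delta)
  y <- with_seed(seed, mu + stats::rnorm(length(x), 0, params$sigma))
  structure(list(
    x = x, y = y, is_control = x == min(x_grid),
    max_conc = exp(max(x_grid)),
    control_x_policy = "simulated grid; lowest level flagged as control",
    herbicide = "synthetic", endpoint = "sgr"
  ), class = "nec_data")
}
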