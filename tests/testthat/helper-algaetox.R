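# shared fixtures built in code

# default synthetic assay: 7 test concentrations x 5 reps around EC50 10
make_assay <- function(seed = 1, noise = TRUE, include_reference = TRUE,
                       n_conc = 7, ec50 = 10, ...) {
  truth <- if (noise) {
    truth_model(curve = list(bottom = 0, top = 100, hill = 1, ec50 = ec50), ...)
  } else {
    truth_model(curve = list(bottom = 0, top = 100, hill = 1, ec50 = ec50),
                noise_cv_density = 0, noise_sd_yield = 0,
                noise_cv_measured = 0, ...)
  }
  simulate_assay(default_design(ec50 = ec50, n_conc = n_conc,
                                include_reference = include_reference),
                 truth, seed = seed)
}

# flat, haloxyfop-like assay: no concentration effect at any tested level
make_flat_assay <- function(seed = 1, max_conc = 4570) {
  des <- assay_design(10^seq(log10(max_conc) - 2, log10(max_conc),
                             length.out = 7))
  truth <- truth_model(curve = list(bottom = 0, top = 100, hill = 1,
                                    ec50 = max_conc * 1e4))
  simulate_assay(des, truth, seed = seed, herbicide = "flat")
}

# minimal hand-built endpoint table for ANOVA/classification unit tests
fake_endpoint_table <- function(values, treatments, concs,
                                roles = NULL, endpoint = "sgr") {
  stopifnot(length(values) == length(treatments))
  roles <- roles %||% ifelse(concs[match(treatments, names(concs))] == 0,
                             "control", "test")
  reps <- data.frame(treatment = treatments, role = roles,
                     replicate = ave(treatments, treatments,
                                     FUN = seq_along),
                     sgr = NA_real_, yield = NA_real_,
                     sgr_inhibition = NA_real_, yield_inhibition = NA_real_,
                     stringsAsFactors = FALSE)
  reps[[endpoint]] <- values
  ctrl_mean <- mean(values[roles == "control"])
  if (!is.finite(ctrl_mean) || ctrl_mean == 0) ctrl_mean <- mean(values)
  reps[[paste0(endpoint, "_inhibition")]] <-
    100 * (ctrl_mean - values) / ctrl_mean
  tr <- data.frame(treatment = names(concs),
                   role = roles[match(names(concs), treatments)],
                   nominal_conc = unname(concs), twa_conc = unname(concs),
                   conc_source = "nominal_fallback",
                   stringsAsFactors = FALSE)
  structure(list(herbicide = "fake", replicates = reps, treatments = tr,
                 control_mean_sgr = ctrl_mean, control_mean_yield = NA_real_,
                 baseline_roles = "control"),
            class = "endpoint_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
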