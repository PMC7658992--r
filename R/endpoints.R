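#' Specific growth rate
#'
#' Logarithmic increase in cell density per day between two time points:
#' \deqn{SGR = (\ln X_j - \ln X_i) / (t_j - t_i)}
#' Negative values (population decline) are allowed.
#'
#' @param x_i,x_j cell densities (cells/mL) at times \code{t_i}, \code{t_j};
#'   must be positive. Vectorised.
#' @param t_i,t_j times in days, \code{t_j > t_i}.
#' @return growth rate in 1/day.
#' @export
#' @examples
#' specific_growth_rate(3000, 2e5, 0, 3) # ~1.40 per day
specific_growth_rate <- function(x_i, x_j, t_i = 0, t_j = 3) {
  if (any(!is.finite(x_i) | x_i <= 0) || any(!is.finite(x_j) | x_j <= 0)) {
    stop("cell densities must be positive and finite", call. = FALSE)
  }
  if (any(t_j <= t_i)) stop("t_j must exceed t_i", call. = FALSE)
  (log(x_j) - log(x_i)) / (t_j - t_i)
}

#' Effective quantum yield of photosystem II
#'
#' Light-adapted PSII photochemical efficiency from a PAM fluorescence pair:
#' \deqn{\Delta F / F_m' = (F_m' - F) / F_m'}
#'
#' @param f light-adapted minimum fluorescence F (instrument units), with
#'   \code{0 <= f <= fm}. Vectorised.
#' @param fm light-adapted maximum fluorescence Fm' (> 0).
#' @return dimensionless yield in [0, 1].
#' @export
#' @examples
#' effective_quantum_yield(261, 500) # 0.478
effective_quantum_yield <- function(f, fm) {
  if (any(!is.finite(fm) | fm <= 0)) stop("Fm' must be > 0", call. = FALSE)
  if (any(!is.finite(f) | f < 0 | f > fm)) {
    stop("F must satisfy 0 <= F <= Fm'", call. = FALSE)
  }
  (fm - f) / fm
}

#' Percent inhibition relative to control
#'
#' \deqn{\%I = 100 (X_{control} - X_{treatment}) / X_{control}}
#' Negative values (stimulation above control) are preserved, never clipped.
#'
#' @param x_control control mean endpoint value (nonzero).
#' @param x_treatment treatment endpoint value. Vectorised.
#' @return percent inhibition.
#' @export
percent_inhibition <- function(x_control, x_treatment) {
  if (any(x_control == 0)) {
    stop("control mean endpoint is zero; inhibition undefined", call. = FALSE)
  }
  100 * (x_control - x_treatment) / x_control
}

#' Time-weighted average exposure concentration
#'
#' Geometric mean of the measured start and end concentrations, the standard
#' time-weighted average for first-order dissipation over the exposure.
#'
#' @param c_start,c_end measured concentrations (ug/L), both positive.
#' @return sqrt(c_start * c_end), ug/L.
#' @export
twa_concentration <- function(c_start, c_end) {
  if (any(!is.finite(c_start) | c_start <= 0) ||
      any(!is.finite(c_end) | c_end <= 0)) {
    stop("measured concentrations must be positive; apply a below-LOQ ",
         "substitution policy before computing the TWA", call. = FALSE)
  }
  sqrt(c_start * c_end)
}

#' Per-replicate endpoint table for a bioassay
#'
#' Computes the biological endpoints for every replicate: 72-h specific
#' growth rate, 24-h effective quantum yield (when fluorescence is present),
#' and percent inhibition of each relative to the mean of the control
#' replicates. Per-treatment exposure is the time-weighted average (geometric
#' mean) of measured start/end concentrations, falling back to the nominal
#' concentration (flagged in \code{conc_source}) when measurements are absent.
#'
#' @param ds an [assay_dataset()].
#' @param pool_solvent_control if TRUE, solvent-control replicates are pooled
#'   with seawater controls for the inhibition baseline. Default FALSE: the
#'   seawater control alone is the baseline.
#' @param loq limit of quantitation (ug/L) or NULL. Measured concentrations
#'   at or below \code{loq} are replaced by \code{loq/2} before the TWA;
#'   without an LOQ, non-positive measured values fall back to nominal.
#' @return object of class \code{endpoint_table}: list with
#'   \code{replicates} (one row per replicate with sgr, yield and their
#'   inhibitions), \code{treatments} (per-treatment twa_conc and its source),
#'   \code{control_mean_sgr}, \code{control_mean_yield}.
#' @export
endpoint_table <- function(ds, pool_solvent_control = FALSE, loq = NULL) {
  stopifnot(inherits(ds, "assay_dataset"))
  issues <- validate_dataset(ds)
  if (length(issues)) {
    stop("dataset fails validation: ", issues[1],
         if (length(issues) > 1) sprintf(" (and %d more)", length(issues) - 1),
         call. = FALSE)
  }
  d <- ds$data
  sgr <- specific_growth_rate(d$cell_density_t0, d$cell_density_t72,
                              0, ds$duration)
  has_fluor <- all(c("fluorescence_F", "fluorescence_Fm") %in% names(d))
  yield <- if (has_fluor) {
    out <- rep(NA_real_, nrow(d))
    ok <- !is.na(d$fluorescence_F) & !is.na(d$fluorescence_Fm)
    out[ok] <- effective_quantum_yield(d$fluorescence_F[ok],
                                       d$fluorescence_Fm[ok])
    out
  } else {
    rep(NA_real_, nrow(d))
  }

  baseline_roles <- if (pool_solvent_control) {
    c("control", "solvent_control")
  } else {
    "control"
  }
  is_ctrl <- d$role %in% baseline_roles
  if (!any(is_ctrl)) is_ctrl <- d$role == "solvent_control"
  control_mean_sgr <- mean(sgr[is_ctrl])
  control_mean_yield <- if (any(is_ctrl & !is.na(yield))) {
    mean(yield[is_ctrl], na.rm = TRUE)
  } else {
    NA_real_
  }

  sgr_inh <- percent_inhibition(control_mean_sgr, sgr)
  yield_inh <- if (!is.na(control_mean_yield)) {
    percent_inhibition(control_mean_yield, yield)
  } else {
    rep(NA_real_, nrow(d))
  }

  reps <- data.frame(
    treatment = d$treatment, role = d$role, replicate = d$replicate,
    sgr = sgr, yield = yield,
    sgr_inhibition = sgr_inh, yield_inhibition = yield_inh,
    stringsAsFactors = FALSE
  )

  # per-treatment exposure metric
  tr_idx <- !duplicated(d$treatment)
  tr <- data.frame(treatment = d$treatment[tr_idx], role = d$role[tr_idx],
                   nominal_conc = d$nominal_conc[tr_idx],
                   stringsAsFactors = FALSE)
  have_meas <- all(c("measured_conc_start", "measured_conc_end") %in% names(d))
  twa <- numeric(nrow(tr))
  src <- character(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    rows <- d$treatment == tr$treatment[k]
    if (tr$role[k] %in% c("control", "solvent_control")) {
      twa[k] <- 0
      src[k] <- "control"
      next
    }
    cs <- if (have_meas) d$measured_conc_start[rows][1] else NA_real_
    ce <- if (have_meas) d$measured_conc_end[rows][1] else NA_real_
    if (!is.null(loq)) {
      if (!is.na(cs) && cs <= loq) cs <- loq / 2
      if (!is.na(ce) && ce <= loq) ce <- loq / 2
    }
    if (!is.na(cs) && !is.na(ce) && cs > 0 && ce > 0) {
      twa[k] <- twa_concentration(cs, ce)
      src[k] <- "measured"
    } else {
      twa[k] <- tr$nominal_conc[k]
      src[k] <- "nominal_fallback"
    }
  }
  tr$twa_conc <- twa
  tr$conc_source <- src

  structure(list(herbicide = ds$herbicide, replicates = reps,
                 treatments = tr, control_mean_sgr = control_mean_sgr,
                 control_mean_yield = control_mean_yield,
                 baseline_roles = baseline_roles),
            class = "endpoint_table")
}

#' @export
print.endpoint_table <- function(x, ...) {
  cat("Endpoint table:", x$herbicide, "\n")
  cat(sprintf("  control mean SGR: %.3f /day", x$control_mean_sgr))
  if (!is.na(x$control_mean_yield)) {
    cat(sprintf(", control mean yield: %.3f", x$control_mean_yield))
  }
  cat("\n")
  agg <- stats::aggregate(sgr_inhibition ~ treatment, x$replicates, mean)
  tab <- merge(x$treatments[c("treatment", "role", "twa_conc")], agg,
               by = "treatment")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an endpoint table to CSV
#'
#' One row per replicate, with the treatment-level TWA concentration joined
#' on. Numbers are written at full precision.
#'
#' @param tbl an [endpoint_table()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_endpoint_csv <- function(tbl, path) {
  stopifnot(inherits(tbl, "endpoint_table"))
  out <- merge(tbl$replicates,
               tbl$treatments[c("treatment", "twa_conc", "conc_source")],
               by = "treatment", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
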