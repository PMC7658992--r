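#' Control performance summary
#'
#' Mean and percent coefficient of variation (CV% = 100 sd/mean, sample sd)
#' of the control replicates' specific growth rate and, when available,
#' effective quantum yield; plus the mean inhibition observed in the
#' reference-toxicant treatment. This is the first half of the assay
#' acceptability report; [check_validity()] completes it.
#'
#' @param tbl an [endpoint_table()].
#' @return object of class \code{qc_report} with the validity flags unset.
#' @export
control_performance <- function(tbl) {
  stopifnot(inherits(tbl, "endpoint_table"))
  reps <- tbl$replicates
  ctrl <- reps[reps$role %in% tbl$baseline_roles, , drop = FALSE]
  if (nrow(ctrl) < 2) {
    stop("at least 2 control replicates are required for QC", call. = FALSE)
  }
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  ref <- reps[reps$role == "reference", , drop = FALSE]
  structure(list(
    herbicide = tbl$herbicide,
    control_n = nrow(ctrl),
    control_mean_sgr = mean(ctrl$sgr),
    control_cv_pct = cv(ctrl$sgr),
    control_mean_yield = if (all(is.na(ctrl$yield))) NA_real_
                         else mean(ctrl$yield, na.rm = TRUE),
    control_cv_yield_pct = if (all(is.na(ctrl$yield))) NA_real_
                           else cv(ctrl$yield[!is.na(ctrl$yield)]),
    reference_inhibition_sgr = if (nrow(ref)) mean(ref$sgr_inhibition)
                               else NA_real_,
    reference_inhibition_yield = if (nrow(ref) && !all(is.na(ref$yield_inhibition)))
                                   mean(ref$yield_inhibition, na.rm = TRUE)
                                 else NA_real_,
    ph_max_increase = NA_real_,
    flags = NULL
  ), class = "qc_report")
}

#' Apply assay validity criteria
#'
#' Completes a [control_performance()] report with the standard growth-test
#' acceptability flags:
#' \itemize{
#'   \item \code{valid_growth}: control mean SGR >= 0.92 /day;
#'   \item \code{valid_cv}: control SGR CV% <= 10;
#'   \item \code{valid_ph}: no treatment's pH rose by more than 1 unit
#'     between 0 h and 72 h (signed increase; decreases never fail);
#'   \item \code{valid}: all of the above.
#' }
#' The reference-toxicant inhibition is reported as a consistency indicator
#' but is not a validity gate.
#'
#' @param qc a \code{qc_report} from [control_performance()].
#' @param phys per-treatment physicochemistry: either an [assay_dataset()]
#'   (its \code{ph_t0}/\code{ph_t72} columns are used) or a data.frame with
#'   columns \code{treatment}, \code{ph_t0}, \code{ph_t72}; NULL skips the
#'   pH criterion (flag passes with a note).
#' @param sgr_min,cv_max,ph_max_rise criterion thresholds (defaults 0.92 /day,
#'   10%, 1 pH unit).
#' @return the completed \code{qc_report} with \code{flags} set.
#' @export
check_validity <- function(qc, phys = NULL, sgr_min = 0.92, cv_max = 10,
                           ph_max_rise = 1) {
  stopifnot(inherits(qc, "qc_report"))
  ph_rise <- NA_real_
  if (!is.null(phys)) {
    pd <- if (inherits(phys, "assay_dataset")) phys$data else phys
    if (all(c("ph_t0", "ph_t72") %in% names(pd))) {
      ok <- !is.na(pd$ph_t0) & !is.na(pd$ph_t72)
      if (any(ok)) ph_rise <- max(pd$ph_t72[ok] - pd$ph_t0[ok])
    }
  }
  qc$ph_max_increase <- ph_rise
  flags <- list(
    valid_growth = list(
      pass = qc$control_mean_sgr >= sgr_min,
      message = sprintf("control mean SGR %.3f /day (criterion >= %.2f)",
                        qc$control_mean_sgr, sgr_min)),
    valid_cv = list(
      pass = qc$control_cv_pct <= cv_max,
      message = sprintf("control SGR CV %.2f%% (criterion <= %g%%)",
                        qc$control_cv_pct, cv_max)),
    valid_ph = list(
      pass = is.na(ph_rise) || ph_rise <= ph_max_rise,
      message = if (is.na(ph_rise)) {
        "pH data absent; criterion not evaluated"
      } else {
        sprintf("max pH increase %.2f units (criterion <= %g)",
                ph_rise, ph_max_rise)
      })
  )
  flags$valid <- list(
    pass = all(vapply(flags, `[[`, logical(1), "pass")),
    message = "all validity criteria met")
  if (!flags$valid$pass) {
    failed <- names(flags)[!vapply(flags, `[[`, logical(1), "pass")]
    flags$valid$message <- paste("failed:", paste(setdiff(failed, "valid"),
                                                  collapse = ", "))
  }
  qc$flags <- flags
  qc
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Assay QC:", x$herbicide, "\n")
  cat(sprintf("  control SGR %.3f /day (CV %.2f%%, n = %d)\n",
              x$control_mean_sgr, x$control_cv_pct, x$control_n))
  if (!is.na(x$control_mean_yield)) {
    cat(sprintf("  control yield %.3f (CV %.2f%%)\n",
                x$control_mean_yield, x$control_cv_yield_pct))
  }
  if (!is.na(x$reference_inhibition_sgr)) {
    cat(sprintf("  reference toxicant inhibition: SGR %.1f%%",
                x$reference_inhibition_sgr))
    if (!is.na(x$reference_inhibition_yield)) {
      cat(sprintf(", yield %.1f%%", x$reference_inhibition_yield))
    }
    cat("\n")
  }
  if (is.null(x$flags)) {
    cat("  validity: not yet evaluated (run check_validity)\n")
  } else {
    for (nm in names(x$flags)) {
      f <- x$flags[[nm]]
      cat(sprintf("  %-12s %s  [%s]\n", nm,
                  if (f$pass) "PASS" else "FAIL", f$message))
    }
  }
  invisible(x)
}
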