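#' Analysis configuration
#'
#' Control list for [run_assay()], analogous to \code{glm.control}: QC
#' thresholds, ECx levels, bootstrap and MCMC settings, and the seed that
#' drives every stochastic step. All downstream functions take their
#' settings from here so a run is fully described by (dataset, config).
#'
#' @param ec_levels ECx levels in percent (default c(10, 50)).
#' @param n_boot bootstrap resamples for ECx confidence intervals
#'   (default 2000; 0 skips the bootstrap).
#' @param nec_chains,nec_iter,nec_burnin MCMC settings for [fit_nec()]
#'   (defaults 4 chains, 10000 iterations, 5000 burn-in).
#' @param nec_endpoints endpoints to fit the NEC model on (default "sgr").
#' @param seed integer master seed.
#' @param pool_solvent_control pool solvent with seawater controls for the
#'   inhibition baseline (default FALSE).
#' @param loq limit of quantitation for measured concentrations (ug/L) or
#'   NULL.
#' @param control_decades control placement for the NEC design (default 1).
#' @param sgr_min,cv_max,ph_max_rise assay validity thresholds
#'   (0.92 /day, 10%, 1 pH unit).
#' @param anova_alpha,max_top_inhibition nonresponse classification rule:
#'   nonresponsive iff ANOVA p >= alpha AND top-concentration inhibition
#'   below the cutoff (defaults 0.05 and 10%).
#' @return list of class \code{assay_config}.
#' @export
assay_config <- function(ec_levels = c(10, 50), n_boot = 2000,
                         nec_chains = 4, nec_iter = 10000, nec_burnin = 5000,
                         nec_endpoints = "sgr", seed = 1,
                         pool_solvent_control = FALSE, loq = NULL,
                         control_decades = 1,
                         sgr_min = 0.92, cv_max = 10, ph_max_rise = 1,
                         anova_alpha = 0.05, max_top_inhibition = 10) {
  structure(as.list(environment()), class = "assay_config")
}

#' Run the full concentration-response analysis on one bioassay
#'
#' Executes the complete pipeline: endpoint computation, assay validity QC,
#' response classification, 4PL ECx estimation with bootstrap intervals,
#' Bayesian NEC estimation, and (when a reference run is supplied) relative
#' potency. Nonresponsive assays skip the curve and threshold fits and
#' report every threshold censored at the maximum tested concentration. QC
#' failure warns but never aborts: the flags travel with the summary and
#' the analyst decides.
#'
#' @param ds an [assay_dataset()].
#' @param config an [assay_config()].
#' @param reference optional \code{assay_run} of the reference compound;
#'   enables ReP computation.
#' @return object of class \code{assay_run}: \code{qc},
#'   \code{endpoints} (the [endpoint_table()]), per-endpoint results in
#'   \code{fits} (each with \code{classification}, \code{fourpl},
#'   \code{ec} estimates), \code{nec} (per NEC endpoint), \code{potency},
#'   \code{provenance}.
#' @export
run_assay <- function(ds, config = assay_config(), reference = NULL) {
  stopifnot(inherits(ds, "assay_dataset"), inherits(config, "assay_config"))
  issues <- validate_dataset(ds)
  if (length(issues)) {
    stop("dataset invalid at stage 'validate': ", issues[1], call. = FALSE)
  }
  tbl <- endpoint_table(ds, pool_solvent_control = config$pool_solvent_control,
                        loq = config$loq)
  qc <- check_validity(control_performance(tbl), ds,
                       sgr_min = config$sgr_min, cv_max = config$cv_max,
                       ph_max_rise = config$ph_max_rise)
  if (!qc$flags$valid$pass) {
    warning("assay failed validity criteria (", qc$flags$valid$message,
            "); results are reported but flagged", call. = FALSE)
  }

  endpoints <- "sgr"
  if (!all(is.na(tbl$replicates$yield))) endpoints <- c("sgr", "yield")

  reps <- merge(tbl$replicates,
                tbl$treatments[c("treatment", "twa_conc")],
                by = "treatment", sort = FALSE)
  test_reps <- reps[reps$role == "test", , drop = FALSE]
  max_conc <- max(test_reps$twa_conc)

  fits <- list()
  for (ep in endpoints) {
    inh <- test_reps[[paste0(ep, "_inhibition")]]
    cls <- classify_response(tbl, ep, alpha = config$anova_alpha,
                             max_top_inhibition = config$max_top_inhibition)
    if (cls$responsive) {
      fp <- fit_4pl(test_reps$twa_conc, inh, ec_levels = config$ec_levels)
      ec <- fp$ec_estimates
      if (config$n_boot > 0) {
        for (i in seq_along(config$ec_levels)) {
          lv <- config$ec_levels[i]
          if (!ec[[i]]$censored) {
            ec[[i]] <- bootstrap_ci(test_reps$twa_conc, inh, level = lv,
                                    n_boot = config$n_boot,
                                    seed = child_seed(config$seed,
                                                      100 + i +
                                                        10 * match(ep, endpoints)))
          }
        }
      }
    } else {
      fp <- NULL
      ec <- lapply(config$ec_levels, function(lv) {
        structure(list(level = lv, value = max_conc, ci_low = NA_real_,
                       ci_high = NA_real_, censored = TRUE),
                  class = "ec_estimate")
      })
      names(ec) <- paste0("EC", config$ec_levels)
    }
    fits[[ep]] <- list(classification = cls, fourpl = fp, ec = ec)
  }

  nec <- list()
  for (ep in intersect(config$nec_endpoints, endpoints)) {
    if (fits[[ep]]$classification$responsive) {
      nd <- nec_design_matrix(tbl, ep,
                              control_decades = config$control_decades)
      nec[[ep]] <- fit_nec(nd, chains = config$nec_chains,
                           iter = config$nec_iter,
                           burnin = config$nec_burnin,
                           seed = child_seed(config$seed,
                                             200 + match(ep, endpoints)))
    } else {
      nec[[ep]] <- censored_nec(max_conc)
    }
  }

  potency <- NULL
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "assay_run"))
    ref_sgr <- reference$fits$sgr$ec$EC50
    ref_yield <- reference$fits$yield$ec$EC50
    potency <- potency_summary(
      ec50_sgr = fits$sgr$ec$EC50,
      ec50_yield = fits$yield$ec$EC50,
      ref_ec50_sgr = ref_sgr, ref_ec50_yield = ref_yield,
      reference_name = reference$herbicide)
  }

  structure(list(
    herbicide = ds$herbicide, qc = qc, endpoints = tbl,
    fits = fits, nec = nec, potency = potency,
    provenance = list(seed = config$seed, config = unclass(config),
                      version = as.character(utils::packageVersion("algaetox")))
  ), class = "assay_run")
}

#' @export
print.assay_run <- function(x, ...) {
  cat("==== Assay run:", x$herbicide, "====\n")
  print(x$qc)
  for (ep in names(x$fits)) {
    f <- x$fits[[ep]]
    cat(sprintf("-- endpoint %s: %s\n", ep,
                if (f$classification$responsive) "responsive" else
                  "nonresponsive (censored thresholds)"))
    for (nm in names(f$ec)) {
      e <- f$ec[[nm]]
      cat(sprintf("   %s = %s ug/L", nm, format_threshold(e$value, e$censored)))
      if (!is.na(e$ci_low)) {
        cat(sprintf(" (95%% CI %s-%s)", format_sigfig(e$ci_low),
                    format_sigfig(e$ci_high)))
      }
      cat("\n")
    }
  }
  for (ep in names(x$nec)) {
    n <- x$nec[[ep]]
    cat(sprintf("   NEC (%s) = %s ug/L", ep,
                format_threshold(n$nec_value, n$censored)))
    if (!n$censored) {
      cat(sprintf(" (95%% CrI %s-%s)", format_sigfig(n$nec_ci[1]),
                  format_sigfig(n$nec_ci[2])))
    }
    cat("\n")
  }
  if (!is.null(x$potency)) print(x$potency)
  invisible(x)
}

#' Serialize an analysis result to disk
#'
#' Writes any of the package's result objects with all numbers at full
#' precision plus display fields rounded to 3 significant figures (censored
#' thresholds rendered as "> max tested"). Tables go to CSV; structured
#' results (full runs, NEC fits) to JSON.
#'
#' @param report a result object ([run_assay()], [fit_4pl()], [fit_nec()],
#'   [endpoint_table()], [potency_summary()], or a plain data.frame).
#' @param path output file path.
#' @param ... unused.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(report, path, ...) UseMethod("write_results")

#' @export
write_results.default <- function(report, path, ...) {
  stop("no write_results method for class ", paste(class(report),
                                                   collapse = "/"),
       call. = FALSE)
}

#' @export
write_results.data.frame <- function(report, path, ...) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.endpoint_table <- function(report, path, ...) {
  write_endpoint_csv(report, path)
}

#' @keywords internal
#' @noRd
ec_row <- function(nm, e) {
  data.frame(estimate = nm, level = e$level, value = e$value,
             ci_low = e$ci_low, ci_high = e$ci_high,
             censored = e$censored,
             display = format_threshold(e$value, e$censored),
             stringsAsFactors = FALSE)
}

#' @export
write_results.fourpl_fit <- function(report, path, ...) {
  cf <- report$coefficients
  rows <- do.call(rbind, c(
    list(data.frame(estimate = names(cf), level = NA_real_,
                    value = unname(cf), ci_low = NA_real_,
                    ci_high = NA_real_, censored = FALSE,
                    display = format_sigfig(unname(cf)),
                    stringsAsFactors = FALSE)),
    Map(ec_row, names(report$ec_estimates), report$ec_estimates)))
  rows <- rbind(rows, data.frame(estimate = "r_squared", level = NA_real_,
                                 value = report$r_squared, ci_low = NA_real_,
                                 ci_high = NA_real_, censored = FALSE,
                                 display = format_sigfig(report$r_squared),
                                 stringsAsFactors = FALSE))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.nec_fit <- function(report, path, ...) {
  out <- list(
    nec_value = report$nec_value,
    nec_ci = report$nec_ci,
    censored = report$censored,
    display = format_threshold(report$nec_value, report$censored),
    max_tested = report$max_conc
  )
  if (!is.null(report$draws)) {
    out$posterior_median <- as.list(coef(report))
    out$diagnostics <- report$diagnostics
    out$settings <- list(chains = report$chains, iter = report$iter,
                         burnin = report$burnin, seed = report$seed)
    out$control_x_policy <- report$data$control_x_policy
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_results.potency_summary <- function(report, path, ...) {
  df <- data.frame(
    quantity = c("rep_sgr", "rep_yield", "ec50_ratio"),
    value = c(report$rep_sgr, report$rep_yield, report$ec50_ratio),
    display = format_sigfig(c(report$rep_sgr, report$rep_yield,
                              report$ec50_ratio)),
    reference = report$reference_name,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.assay_run <- function(report, path, ...) {
  ec_list <- function(e) {
    list(level = e$level, value = e$value, ci_low = e$ci_low,
         ci_high = e$ci_high, censored = e$censored,
         display = format_threshold(e$value, e$censored))
  }
  out <- list(
    herbicide = report$herbicide,
    qc = list(
      control_mean_sgr = report$qc$control_mean_sgr,
      control_cv_pct = report$qc$control_cv_pct,
      control_mean_yield = report$qc$control_mean_yield,
      reference_inhibition_sgr = report$qc$reference_inhibition_sgr,
      reference_inhibition_yield = report$qc$reference_inhibition_yield,
      ph_max_increase = report$qc$ph_max_increase,
      flags = lapply(report$qc$flags, function(f)
        list(pass = f$pass, message = f$message))
    ),
    endpoints = lapply(report$fits, function(f) {
      list(responsive = f$classification$responsive,
           anova_p = f$classification$p_value,
           top_inhibition = f$classification$top_inhibition,
           r_squared = if (!is.null(f$fourpl)) f$fourpl$r_squared else NULL,
           ec = lapply(f$ec, ec_list))
    }),
    nec = lapply(report$nec, function(n) {
      list(nec_value = n$nec_value, nec_ci = n$nec_ci,
           censored = n$censored,
           display = format_threshold(n$nec_value, n$censored))
    }),
    potency = if (!is.null(report$potency)) {
      list(rep_sgr = report$potency$rep_sgr,
           rep_yield = report$potency$rep_yield,
           ec50_ratio = report$potency$ec50_ratio,
           reference = report$potency$reference_name)
    } else NULL,
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
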