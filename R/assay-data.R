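#' Construct a bioassay dataset
#'
#' An \code{assay_dataset} holds one herbicide bioassay in long format: one
#' row per replicate culture, carrying cell densities at 0 h and 72 h,
#' optional light-adapted fluorescence pairs (F, Fm') at 24 h, nominal and
#' (optionally) measured start/end exposure concentrations, and optional
#' per-treatment physicochemistry.
#'
#' @param herbicide character scalar naming the test compound.
#' @param data data.frame with one row per replicate. Mandatory columns:
#'   \code{treatment}, \code{role} (one of \code{"control"},
#'   \code{"solvent_control"}, \code{"reference"}, \code{"test"}),
#'   \code{nominal_conc} (ug/L), \code{replicate}, \code{cell_density_t0},
#'   \code{cell_density_t72} (cells/mL). Optional columns:
#'   \code{fluorescence_F}, \code{fluorescence_Fm},
#'   \code{measured_conc_start}, \code{measured_conc_end} (ug/L),
#'   \code{ph_t0}, \code{ph_t72}, \code{salinity}, \code{dissolved_oxygen},
#'   \code{temperature}.
#' @param duration exposure duration in days (default 3).
#'
#' @return object of class \code{assay_dataset}.
#' @seealso [read_assay_csv()], [validate_dataset()], [endpoint_table()]
#' @export
assay_dataset <- function(herbicide, data, duration = 3) {
  stopifnot(is.character(herbicide), length(herbicide) == 1L,
            is.data.frame(data), is.numeric(duration), duration > 0)
  missing_cols <- setdiff(assay_mandatory_cols(), names(data))
  if (length(missing_cols)) {
    stop("assay data lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  # canonical row order so that downstream results never depend on input order
  ord <- order(data$treatment, data$replicate)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(list(herbicide = herbicide, duration = duration, data = data),
            class = "assay_dataset")
}

#' @keywords internal
#' @noRd
assay_mandatory_cols <- function() {
  c("treatment", "role", "nominal_conc", "replicate",
    "cell_density_t0", "cell_density_t72")
}

#' @keywords internal
#' @noRd
assay_optional_cols <- function() {
  c("fluorescence_F", "fluorescence_Fm",
    "measured_conc_start", "measured_conc_end",
    "ph_t0", "ph_t72", "salinity", "dissolved_oxygen", "temperature")
}

#' @keywords internal
#' @noRd
assay_roles <- function() c("control", "solvent_control", "reference", "test")

#' Read a bioassay from a long-format CSV file
#'
#' One CSV per assay, one row per replicate. Column \code{herbicide} and
#' \code{duration}, if present, populate the dataset metadata; otherwise the
#' file name stem and 3 days are used. Concentration columns are converted
#' to ug/L according to \code{units}.
#'
#' @param path CSV file path.
#' @param units units of the concentration columns in the file: one of
#'   \code{"ug/L"} (default), \code{"ng/L"}, \code{"mg/L"}.
#' @return an [assay_dataset()].
#' @export
read_assay_csv <- function(path, units = c("ug/L", "ng/L", "mg/L")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(assay_mandatory_cols(), names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("nominal_conc", "cell_density_t0", "cell_density_t72",
                          assay_optional_cols()), names(raw))
  for (cc in num_cols) {
    if (is.character(raw[[cc]])) {
      conv <- suppressWarnings(as.numeric(raw[[cc]]))
      bad <- which(!is.na(raw[[cc]]) & raw[[cc]] != "" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                     cc, bad[1], raw[[cc]][bad[1]]), call. = FALSE)
      }
      raw[[cc]] <- conv
    }
  }
  scale <- switch(units, "ug/L" = 1, "ng/L" = 1e-3, "mg/L" = 1e3)
  for (cc in intersect(c("nominal_conc", "measured_conc_start",
                         "measured_conc_end"), names(raw))) {
    raw[[cc]] <- raw[[cc]] * scale
  }
  herbicide <- if ("herbicide" %in% names(raw)) {
    as.character(raw$herbicide[1])
  } else {
    sub("\\.csv$", "", basename(path))
  }
  duration <- if ("duration" %in% names(raw)) as.numeric(raw$duration[1]) else 3
  raw$herbicide <- NULL
  raw$duration <- NULL
  ds <- assay_dataset(herbicide, raw, duration = duration)
  if (!any(ds$data$role %in% c("control", "solvent_control"))) {
    stop("dataset contains no control group", call. = FALSE)
  }
  ds
}

#' Write a bioassay dataset to CSV
#'
#' Inverse of [read_assay_csv()]: emits the long-format CSV (always in ug/L)
#' with \code{herbicide} and \code{duration} columns included so the file is
#' self-describing.
#'
#' @param ds an [assay_dataset()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_assay_csv <- function(ds, path) {
  stopifnot(inherits(ds, "assay_dataset"))
  out <- ds$data
  out <- cbind(herbicide = ds$herbicide, duration = ds$duration, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structural validation of a bioassay dataset
#'
#' Checks the dataset invariants and returns a character vector of issue
#' descriptions, empty when the dataset is well formed. Unlike the
#' constructors this never raises: it is meant for QC-style reporting.
#'
#' Rules checked: positive cell densities; fluorescence pairs present or
#' absent together with Fm' >= F >= 0; controls at nominal concentration 0;
#' positive measured concentrations where present; at least 2 replicates per
#' treatment; exactly one control group per control role; unique
#' (treatment, replicate) ids; pH within [0, 14]; salinity >= 0.
#'
#' @param ds an [assay_dataset()].
#' @return character vector of issues (zero length if valid).
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "assay_dataset"))
  d <- ds$data
  issues <- character(0)
  note <- function(fmt, ...) sprintf(fmt, ...)
  tag <- function(i) sprintf("treatment '%s' replicate '%s'",
                             d$treatment[i], d$replicate[i])

  bad_role <- !d$role %in% assay_roles()
  for (i in which(bad_role)) {
    issues <- c(issues, note("%s: unknown role '%s'", tag(i), d$role[i]))
  }
  for (i in which(!(d$cell_density_t0 > 0) | !(d$cell_density_t72 > 0))) {
    issues <- c(issues, note("%s: non-positive cell density", tag(i)))
  }
  has_F <- "fluorescence_F" %in% names(d)
  has_Fm <- "fluorescence_Fm" %in% names(d)
  if (has_F != has_Fm) {
    issues <- c(issues,
                "fluorescence_F and fluorescence_Fm must both be present or both absent")
  } else if (has_F) {
    pair_na <- is.na(d$fluorescence_F) != is.na(d$fluorescence_Fm)
    for (i in which(pair_na)) {
      issues <- c(issues, note("%s: fluorescence F/Fm' must be missing as a pair",
                               tag(i)))
    }
    ok <- !is.na(d$fluorescence_F) & !is.na(d$fluorescence_Fm)
    viol <- ok & (d$fluorescence_F < 0 | d$fluorescence_Fm < d$fluorescence_F)
    for (i in which(viol)) {
      issues <- c(issues, note("%s: requires Fm' >= F >= 0 (F=%g, Fm'=%g)",
                               tag(i), d$fluorescence_F[i], d$fluorescence_Fm[i]))
    }
  }
  ctrl <- d$role %in% c("control", "solvent_control")
  for (i in which(ctrl & d$nominal_conc != 0)) {
    issues <- c(issues, note("%s: control must have nominal_conc = 0", tag(i)))
  }
  for (cc in intersect(c("measured_conc_start", "measured_conc_end"), names(d))) {
    for (i in which(!is.na(d[[cc]]) & d[[cc]] <= 0)) {
      issues <- c(issues, note("%s: %s must be > 0 when present", tag(i), cc))
    }
  }
  n_rep <- table(d$treatment)
  for (tr in names(n_rep)[n_rep < 2]) {
    issues <- c(issues,
                note("treatment '%s': fewer than 2 replicates (n = %d)",
                     tr, as.integer(n_rep[[tr]])))
  }
  for (r in c("control", "solvent_control")) {
    ntr <- length(unique(d$treatment[d$role == r]))
    if (ntr > 1) {
      issues <- c(issues,
                  note("more than one treatment group with role '%s'", r))
    }
  }
  if (!any(ctrl)) issues <- c(issues, "dataset has no control group")
  dup <- duplicated(d[c("treatment", "replicate")])
  for (i in which(dup)) {
    issues <- c(issues, note("%s: duplicated replicate id", tag(i)))
  }
  if ("ph_t0" %in% names(d)) {
    for (i in which(!is.na(d$ph_t0) & (d$ph_t0 < 0 | d$ph_t0 > 14))) {
      issues <- c(issues, note("%s: ph_t0 outside [0, 14]", tag(i)))
    }
  }
  if ("ph_t72" %in% names(d)) {
    for (i in which(!is.na(d$ph_t72) & (d$ph_t72 < 0 | d$ph_t72 > 14))) {
      issues <- c(issues, note("%s: ph_t72 outside [0, 14]", tag(i)))
    }
  }
  if ("salinity" %in% names(d)) {
    for (i in which(!is.na(d$salinity) & d$salinity < 0)) {
      issues <- c(issues, note("%s: negative salinity", tag(i)))
    }
  }
  sort(unique(issues))
}

#' @export
print.assay_dataset <- function(x, ...) {
  d <- x$data
  cat("Bioassay dataset:", x$herbicide, "\n")
  cat(sprintf("  %d treatments, %d replicate records, %g-day exposure\n",
              length(unique(d$treatment)), nrow(d), x$duration))
  roles <- table(d$role[!duplicated(d$treatment)])
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "),
      "\n")
  if ("fluorescence_F" %in% names(d)) {
    cat("  fluorescence endpoint present\n")
  }
  invisible(x)
}
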