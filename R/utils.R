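# internal helpers shared across the package

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points route through
# this so that (inputs, seed) fully determine outputs.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept within
# 32-bit integer range.
#' @keywords internal
#' @noRd
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103L + 7919L * as.double(stream)) %% 2147483647
}

# Display rounding used in serialized reports: 3 significant figures,
# plain decimal notation.
#' @keywords internal
#' @noRd
format_sigfig <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", format(signif(x, digits), scientific = FALSE,
                                trim = TRUE, drop0trailing = TRUE))
}

# Censored thresholds are displayed as "> <max tested>", matching the
# reporting convention for nonresponsive assays.
#' @keywords internal
#' @noRd
format_threshold <- function(value, censored, digits = 3) {
  out <- format_sigfig(value, digits)
  out[censored] <- paste0("> ", format_sigfig(value[censored], digits))
  out
}

#' @keywords internal
#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
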