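# Internal helpers shared across modules.

# data.table is used via :: only; declare awareness for [.data.table
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all integer and fixed-decimal
#' display values, so that e.g. 6.5 blocks per contig prints as 7.
#' `base::round()` rounds half to even, which does not match the table
#' conventions used throughout the package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse strings that must be integer-valued; returns NA where they are not.
.as_int <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  v[!is.na(v) & v != floor(v)] <- NA_real_
  v
}

.is_intlike <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v) & v == floor(v)
}

.is_numlike <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v)
}

# Stable order of first appearance.
.first_appearance <- function(x) unique(x)

.msg <- function(...) message("[blockmapr] ", ...)
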