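#' ISSCAAP product groups used throughout the package
#'
#' The eight coarse product groups of the International Standard Statistical
#' Classification of Aquatic Animals and Plants (ISSCAAP) under which
#' food-balance sheets report seafood quantities. Every `product_group`
#' column in the package is restricted to this closed set.
#'
#' @return Character vector of the eight group names, in canonical order.
#' @export
#' @examples
#' isscaap_groups()
isscaap_groups <- function() {
  c(
    "Freshwater & Diadromous Fish",
    "Pelagic Fish",
    "Demersal Fish",
    "Marine Fish NEI",
    "Crustaceans",
    "Cephalopods",
    "Molluscs excl. Cephalopods",
    "Aquatic Animals NEI"
  )
}

#' UN-style geo-region labels used by the gap-filling model
#'
#' A fixed set of coarse geographic region labels attached to every country
#' as a categorical covariate of the FMI gap-filling regression.
#'
#' @return Character vector of region labels.
#' @export
geo_regions <- function() {
  c("Africa", "Americas", "Asia", "Europe", "Oceania")
}

# Label used for per-country results aggregated over product groups.
AGGREGATE_GROUP <- "AGGREGATE"

# Tolerance under which weight vectors are renormalized rather than rejected.
WEIGHT_TOL <- 1e-9

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_schema <- function(msg, ...) {
  abort(msg, class = "seatrace_schema_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "seatrace_validation_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "seatrace_config_error", ...)
}

# Check a data frame has exactly the expected columns (order-insensitive),
# naming any that are missing.
check_columns <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_nonneg <- function(df, cols, what) {
  for (col in cols) {
    x <- df[[col]]
    bad <- which(!is.na(x) & x < 0)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "%s: negative %s at row(s) %s",
        what, col, paste(head(bad, 5), collapse = ", ")
      ))
    }
  }
  invisible(df)
}
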