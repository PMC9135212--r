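#' Expected counts by indirect standardization
#'
#' Fills the expected-count column E_i = r * n_i, where the reference
#' rate r = sum(y) / sum(n) is computed over the standardization stratum:
#' each period separately (the default, matching per-year SIR maps) or
#' the whole panel when `stratify_by_period = FALSE`. Within every
#' stratum the expected counts then sum exactly to the observed counts.
#'
#' @param panel data.frame with columns `y` (observed counts),
#'   `population`, and a period column (`time`, `year` or `period`).
#' @param stratify_by_period compute the reference rate within each
#'   period (default TRUE) or pooled over the panel.
#' @return the panel with an `E` column added.
#' @export
expected_counts <- function(panel, stratify_by_period = TRUE) {
  if (!all(c("y", "population") %in% names(panel)))
    stop("panel needs columns 'y' and 'population'")
  if (any(!is.finite(panel$population) | panel$population <= 0))
    stop("populations must be strictly positive; drop or fix ",
         "zero-population areas first (see drop_zero_population)")
  period_col <- intersect(c("time", "year", "period"), names(panel))[1]
  if (stratify_by_period && is.na(period_col))
    stop("no period column ('time', 'year' or 'period') found")

  if (stratify_by_period) {
    strata <- panel[[period_col]]
  } else {
    strata <- rep(1L, nrow(panel))
  }
  r <- tapply(panel$y, strata, sum) / tapply(panel$population, strata, sum)
  if (any(!is.finite(r)))
    stop("zero total population in a standardization stratum")
  panel$E <- as.numeric(r[as.character(strata)]) * panel$population
  panel
}

#' Standardized incidence ratios
#'
#' SIR = y / E per row: the ratio of observed to expected counts under
#' indirect standardization. SIR equals 1 wherever an area's rate matches
#' the reference rate of its stratum; zero observed counts give SIR 0.
#'
#' @param panel data.frame with columns `y` and `E` (run
#'   [expected_counts()] first).
#' @return the panel with a `sir` column added.
#' @export
sir <- function(panel) {
  if (is.null(panel$E))
    stop("no 'E' column: run expected_counts() on the panel first")
  if (any(!is.finite(panel$E) | panel$E <= 0))
    stop("expected counts must be positive and finite")
  panel$sir <- panel$y / panel$E
  panel
}

#' Crude rate per 100,000 population
#'
#' The display convention for choropleth exports: observed count divided
#' by population, times 1e5.
#'
#' @param panel data.frame with columns `y` and `population`.
#' @return the panel with a `rate_per_100k` column added.
#' @export
rate_per_100k <- function(panel) {
  if (!all(c("y", "population") %in% names(panel)))
    stop("panel needs columns 'y' and 'population'")
  panel$rate_per_100k <- 1e5 * panel$y / panel$population
  panel
}

#' Drop rows with non-positive population
#'
#' Pre-filter for real-data dialects where uninhabited administrative
#' areas (parks, airports) carry zero population. The number of dropped
#' rows is reported via a message and an attribute.
#'
#' @param panel data.frame with a `population` column.
#' @return filtered panel with attribute `n_dropped`.
#' @export
drop_zero_population <- function(panel) {
  bad <- !is.finite(panel$population) | panel$population <= 0
  if (any(bad))
    message("dropping ", sum(bad), " row(s) with non-positive population")
  out <- panel[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  out
}
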