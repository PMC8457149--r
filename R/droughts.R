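#' Flag extreme hydrological droughts by day of year
#'
#' A day is an extreme hydrological drought at depth `z` when the
#' realization-mean soil water potential is strictly more negative than the
#' given percentile (default the 5th) of that day-of-year's values pooled
#' across years. The climatology therefore needs at least two years. Years are
#' 365 days (no leap days).
#'
#' @param ensemble a `wp_ensemble`, or a numeric matrix/vector of water
#'   potentials: a layer x day matrix, or a daily vector for a single layer
#'   (already the realization mean in either case).
#' @param layer layer index at which to flag (ignored for a vector input).
#' @param percentile percentile of the day-of-year pool, in (0, 100).
#' @param census_interval_years if not `NULL`, also report counts of flagged
#'   days per consecutive census interval of this many years.
#' @return List with `flags` (years x 365 logical matrix), `threshold`
#'   (length-365 percentile by day of year), and `interval_counts`
#'   (data.frame `interval`, `n_flagged`) when requested.
#' @export
flag_droughts <- function(ensemble, layer = 1, percentile = 5,
                          census_interval_years = NULL) {
  if (inherits(ensemble, "wp_ensemble")) {
    series <- ensemble_mean_psi(ensemble)[layer, ]
  } else if (is.matrix(ensemble)) {
    series <- ensemble[layer, ]
  } else {
    series <- as.numeric(ensemble)
  }
  if (length(series) %% 365 != 0)
    stop("series length must be a whole number of 365-day years")
  n_years <- length(series) / 365
  if (n_years < 2) stop("drought climatology requires at least 2 years")
  by_year <- matrix(series, nrow = n_years, ncol = 365, byrow = TRUE)
  threshold <- apply(by_year, 2, stats::quantile, probs = percentile / 100,
                     names = FALSE)
  flags <- sweep(by_year, 2, threshold, `<`)
  out <- list(flags = flags, threshold = threshold)
  if (!is.null(census_interval_years)) {
    iv <- ceiling(seq_len(n_years) / census_interval_years)
    out$interval_counts <- data.frame(
      interval = sort(unique(iv)),
      n_flagged = as.integer(tapply(rowSums(flags), iv, sum)))
  }
  out
}
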