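#' Latin Hypercube sample of soil parameter space
#'
#' Stratified sample: for each parameter, exactly one draw falls in each of
#' the `n` equal-probability strata of its `[lo, hi]` range.
#'
#' @param n number of draws (>= 1).
#' @param ranges data.frame with columns `param`, `lo`, `hi`
#'   (default [soil_param_ranges()]).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame of `n` rows, one column per parameter.
#' @export
lhs_sample <- function(n, ranges = soil_param_ranges(), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (!all(c("param", "lo", "hi") %in% names(ranges))) stop("ranges needs param, lo, hi")
  if (any(ranges$lo >= ranges$hi)) stop("each range must have lo < hi")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, nrow(ranges))
  draws <- sweep(u, 2, ranges$hi - ranges$lo, `*`)
  draws <- sweep(draws, 2, ranges$lo, `+`)
  draws <- as.data.frame(draws)
  names(draws) <- ranges$param
  draws
}

#' Define an observation stream for calibration
#'
#' A stream pairs an observed daily series with an extractor that pulls the
#' matching simulated series out of a [run_column()] state, e.g. volumetric
#' water content at a given layer, daily discharge, or daily ET.
#'
#' @param name label for the stream.
#' @param values observed values (non-empty numeric).
#' @param extractor `function(column_state) -> numeric` of the same length.
#' @param units units of the observed values (documentation only).
#' @return An `obs_stream` object.
#' @export
obs_stream <- function(name, values, extractor, units = "") {
  if (length(values) == 0) stop("observation stream '", name, "' is empty")
  stopifnot(is.function(extractor))
  structure(list(name = name, values = as.numeric(values),
                 extractor = extractor, units = units), class = "obs_stream")
}

#' Extractors for common observation streams
#'
#' Convenience constructors for the three stream types the water balance is
#' calibrated against: volumetric water content at a soil layer, daily
#' discharge, and daily evapotranspiration.
#'
#' @param layer layer index for the moisture stream.
#' @name extractors
#' @return A `function(column_state) -> numeric`.
#' @export
extract_vwc <- function(layer) {
  force(layer)
  function(state) state$theta[layer, ]
}

#' @rdname extractors
#' @export
extract_discharge <- function() function(state) state$discharge

#' @rdname extractors
#' @export
extract_et <- function() function(state) state$et

#' Standardized-RMSE calibration objective for one run
#'
#' Mean over streams of RMSE between observed and simulated series divided by
#' the standard deviation of the observed stream (equal weighting of streams).
#'
#' @param state a [run_column()] result.
#' @param observations list of [obs_stream()] objects.
#' @return Scalar objective (0 for a perfect fit).
#' @export
calibration_objective <- function(state, observations) {
  vapply(observations, function(s) {
    sim <- s$extractor(state)
    if (length(sim) != length(s$values))
      stop("stream '", s$name, "': simulated length ", length(sim),
           " != observed length ", length(s$values))
    sdo <- stats::sd(s$values)
    if (!is.finite(sdo) || sdo == 0)
      stop("stream '", s$name, "' has zero variance: cannot standardize")
    sqrt(mean((sim - s$values)^2)) / sdo
  }, numeric(1)) |> mean()
}

#' Calibrate the soil column against observation streams
#'
#' Runs the water balance for every parameter draw, scores each run with the
#' equally weighted standardized-RMSE objective, and keeps the `k` best
#' members as the water-potential ensemble used downstream (the field-scale
#' workflow is 5000 draws, top 100).
#'
#' @param draws parameter table from [lhs_sample()].
#' @param forcing daily forcing data.frame (`precip_mm`, `vpd_kpa`).
#' @param observations list of [obs_stream()] objects.
#' @param k ensemble size to retain (<= nrow(draws)).
#' @param grid a [soil_grid()].
#' @param spinup_years spin-up passed to [run_column()].
#' @return A `wp_ensemble`: list with `psi` array
#'   (realization x layer x day), `params` (data.frame of the k members,
#'   best first), `objective` (ascending), `grid`.
#' @export
calibrate <- function(draws, forcing, observations, k, grid = soil_grid(),
                      spinup_years = 0) {
  if (k > nrow(draws)) stop("k must not exceed the number of draws")
  if (length(observations) == 0) stop("no observation streams supplied")
  obj <- numeric(nrow(draws))
  for (i in seq_len(nrow(draws))) {
    p <- as_soil_params(draws[i, ])
    state <- run_column(p, forcing, grid, spinup_years = spinup_years)
    obj[i] <- calibration_objective(state, observations)
  }
  top <- order(obj)[seq_len(k)]
  n_day <- nrow(forcing)
  psi <- array(NA_real_, dim = c(k, length(grid$z), n_day))
  for (j in seq_along(top)) {
    p <- as_soil_params(draws[top[j], ])
    psi[j, , ] <- run_column(p, forcing, grid, spinup_years = spinup_years)$psi
  }
  structure(list(psi = psi, params = draws[top, , drop = FALSE],
                 objective = obj[top], objective_all = obj, grid = grid),
            class = "wp_ensemble")
}

as_soil_params <- function(row) {
  p <- unlist(row[soil_param_ranges()$param])
  validate_soil_params(p)
  class(p) <- "soil_params"
  p
}

#' @export
print.wp_ensemble <- function(x, ...) {
  cat(sprintf("Soil water potential ensemble: %d realizations x %d layers x %d days\n",
              dim(x$psi)[1], dim(x$psi)[2], dim(x$psi)[3]))
  cat(sprintf("  best objective %.4g, worst retained %.4g\n",
              min(x$objective), max(x$objective)))
  invisible(x)
}

#' Realization-mean water potential by layer and day
#'
#' @param ensemble a `wp_ensemble`.
#' @return Matrix layer x day of the mean over realizations.
#' @export
ensemble_mean_psi <- function(ensemble) {
  stopifnot(inherits(ensemble, "wp_ensemble"))
  apply(ensemble$psi, c(2, 3), mean)
}
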