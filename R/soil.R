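#' Soil grid with exponentially spaced node depths
#'
#' The default grid is the 13-node column used throughout:
#' Z = (0.01, 0.03, 0.06, 0.12, 0.21, 0.37, 0.62, 1, 1.7, 2.9, 4.7, 7.8, 13) m.
#' Layer interfaces are placed at arithmetic midpoints of adjacent nodes, with
#' the top interface at 0 m and the bottom at 15 m, so each node sits inside
#' its layer and layer thicknesses are positive.
#'
#' @param z node depths in m, strictly increasing, all > 0.
#' @param bottom depth of the bottom interface, m (> max(z)).
#' @return A `soil_grid`: list with `z` (node depths), `interfaces`
#'   (length(z)+1), and `dz` (layer thicknesses, m).
#' @export
soil_grid <- function(z = c(0.01, 0.03, 0.06, 0.12, 0.21, 0.37, 0.62,
                            1, 1.7, 2.9, 4.7, 7.8, 13),
                      bottom = 15) {
  if (any(diff(z) <= 0) || any(z <= 0)) stop("node depths must be positive and strictly increasing")
  if (bottom <= max(z)) stop("bottom interface must lie below the deepest node")
  interfaces <- c(0, (z[-length(z)] + z[-1]) / 2, bottom)
  structure(list(z = z, interfaces = interfaces, dz = diff(interfaces)),
            class = "soil_grid")
}

#' Parameters of the layered soil water balance
#'
#' A 9-parameter bucket column with Campbell retention and conductivity.
#' The parameters play the roles of the land-surface analogues they are
#' named for: `k_sat0` and `k_efold` set the hydraulic-conductivity profile
#' (HKSAT role, decaying with depth), `k_adj` is a dimensionless conductivity
#' multiplier accounting for macroporosity and direct flow paths (HKSAT_ADJ
#' role), `root_efold` regulates the depth of the root water-uptake profile
#' (root-distribution role), and `et_scalar` scales atmospheric demand, the
#' stomatal-slope role.
#'
#' @param k_sat0 saturated conductivity at the surface, mm d-1 (> 0).
#' @param k_efold e-folding depth of conductivity decline, m (> 0).
#' @param k_adj conductivity adjustment multiplier (> 0).
#' @param b Campbell retention exponent (> 0).
#' @param theta_sat saturated volumetric moisture, cm3 cm-3, in (0, 1).
#' @param psi_sat air-entry potential, MPa, < 0 (near zero).
#' @param root_efold e-folding depth of the root uptake profile, m (> 0).
#' @param intercept_frac fraction of rainfall lost to canopy interception, [0, 1].
#' @param et_scalar evaporative demand per unit VPD, mm d-1 kPa-1 (>= 0).
#' @return A named numeric vector of class `soil_params`.
#' @export
soil_params <- function(k_sat0 = 300, k_efold = 2, k_adj = 1, b = 5,
                        theta_sat = 0.45, psi_sat = -0.001, root_efold = 0.3,
                        intercept_frac = 0.15, et_scalar = 5) {
  p <- c(k_sat0 = k_sat0, k_efold = k_efold, k_adj = k_adj, b = b,
         theta_sat = theta_sat, psi_sat = psi_sat, root_efold = root_efold,
         intercept_frac = intercept_frac, et_scalar = et_scalar)
  validate_soil_params(p)
  class(p) <- "soil_params"
  p
}

validate_soil_params <- function(p) {
  need <- c("k_sat0", "k_efold", "k_adj", "b", "theta_sat", "psi_sat",
            "root_efold", "intercept_frac", "et_scalar")
  if (!all(need %in% names(p))) stop("missing soil parameters: ",
                                     paste(setdiff(need, names(p)), collapse = ", "))
  if (p[["k_sat0"]] <= 0 || p[["k_efold"]] <= 0 || p[["k_adj"]] <= 0)
    stop("conductivity parameters must be positive")
  if (p[["b"]] <= 0) stop("retention exponent b must be positive")
  if (p[["theta_sat"]] <= 0 || p[["theta_sat"]] >= 1) stop("theta_sat must be in (0, 1)")
  if (p[["psi_sat"]] >= 0) stop("air-entry potential must be negative")
  if (p[["root_efold"]] <= 0) stop("root e-folding depth must be positive")
  if (p[["intercept_frac"]] < 0 || p[["intercept_frac"]] > 1)
    stop("interception fraction must be in [0, 1]")
  if (p[["et_scalar"]] < 0) stop("ET demand scalar must be non-negative")
  invisible(p)
}

#' Default prior ranges of the soil parameters for ensemble calibration
#'
#' Wide, literature-plausible ranges for a seasonally wet tropical clay soil;
#' used as the Latin-Hypercube sampling box in [calibrate()].
#'
#' @return A data.frame with columns `param`, `lo`, `hi`.
#' @export
soil_param_ranges <- function() {
  data.frame(
    param = c("k_sat0", "k_efold", "k_adj", "b", "theta_sat", "psi_sat",
              "root_efold", "intercept_frac", "et_scalar"),
    lo = c(50, 1.0, 0.3, 3, 0.35, -0.010, 0.2, 0.05, 2),
    hi = c(800, 5.0, 3.0, 10, 0.55, -0.0005, 1.5, 0.30, 8),
    stringsAsFactors = FALSE
  )
}

#' Campbell soil water retention: water potential from moisture
#'
#' \deqn{\Psi(\theta) = \psi_{sat} (\theta/\theta_{sat})^{-b}}
#' Strictly increasing in moisture, equal to the air-entry potential at
#' saturation.
#'
#' @param theta volumetric moisture, cm3 cm-3, in (0, theta_sat].
#' @param params a [soil_params()] vector.
#' @return Water potential, MPa (<= psi_sat < 0).
#' @export
retention_psi <- function(theta, params) {
  validate_soil_params(params)
  if (any(theta <= 0)) stop("moisture must be positive")
  if (any(theta > params[["theta_sat"]] * (1 + 1e-12)))
    stop("moisture exceeds saturation")
  params[["psi_sat"]] * (pmin(theta, params[["theta_sat"]]) /
                           params[["theta_sat"]])^(-params[["b"]])
}

#' Run the daily layered soil water balance
#'
#' Explicit daily update over the soil column. Gravity drainage moves water
#' held above field capacity (0.55 saturation) downward at rate
#' \eqn{K(\theta, z) = K_{sat,0} e^{-z/efold}\,adj\,(\theta/\theta_{sat})^{2b+3}},
#' with fluxes evaluated on the start-of-day state so a wetting pulse advances
#' one layer per day; 30% of each layer's drainage leaves laterally as
#' interflow to the stream (counted in discharge, together with drainage out
#' of the bottom layer). Capillary redistribution exchanges water between
#' adjacent layers at 2 mm d-1 per unit relative-saturation difference,
#' decaying with depth on the conductivity e-folding length. Atmospheric
#' demand `et_scalar * VPD` is met 30% by surface evaporation from the top
#' layer and 70% by transpiration extracted with root weight
#' \eqn{\propto e^{-z/root\_efold} dz}; both are throttled linearly between
#' 0.5 saturation and the residual moisture 0.25 saturation. Throughfall
#' (after canopy interception, which counts toward ET) infiltrates top-down
#' up to saturation, capped by the surface saturated conductivity; the excess
#' is surface runoff. Water potential from [retention_psi()]. The daily water
#' balance closes exactly by construction and is asserted to 1e-6 relative
#' tolerance.
#'
#' @param params a [soil_params()] vector.
#' @param forcing data.frame with daily columns `precip_mm` and `vpd_kpa`
#'   (non-negative).
#' @param grid a [soil_grid()].
#' @param spinup_years number of times the first 365 days are re-run before
#'   recording starts, to move the column off its nominal initial state.
#' @param theta_init initial moisture as a fraction of saturation.
#' @return A `column_state`: list with matrices `theta` and `psi`
#'   (layer x day), daily vectors `et`, `runoff`, `discharge` (mm d-1),
#'   the `grid`, `params`, and the relative water-balance residual `balance`.
#' @export
run_column <- function(params, forcing, grid = soil_grid(), spinup_years = 0,
                       theta_init = 0.75) {
  validate_soil_params(params)
  stopifnot(inherits(grid, "soil_grid"))
  if (!all(c("precip_mm", "vpd_kpa") %in% names(forcing)))
    stop("forcing must have columns precip_mm and vpd_kpa")
  precip <- as.numeric(forcing$precip_mm)
  vpd <- as.numeric(forcing$vpd_kpa)
  if (any(!is.finite(precip)) || any(!is.finite(vpd)))
    stop("forcing must be complete (finite) daily series")
  if (any(precip < 0) || any(vpd < 0)) stop("negative precipitation or VPD in forcing")
  if (spinup_years > 0 && length(precip) < 365)
    stop("spin-up requires at least one year of forcing")

  out <- column_core(as.numeric(params)[match(
    c("k_sat0", "k_efold", "k_adj", "b", "theta_sat", "psi_sat",
      "root_efold", "intercept_frac", "et_scalar"), names(params))],
    precip, vpd, grid$z, grid$dz, as.integer(spinup_years), theta_init)

  storage0 <- out$storage0
  storage1 <- sum(out$theta[, ncol(out$theta)] * grid$dz * 1000)
  cum_in <- sum(precip)
  resid <- cum_in - (storage1 - storage0) -
    sum(out$et) - sum(out$runoff) - sum(out$discharge)
  rel <- abs(resid) / max(cum_in, 1)
  if (rel > 1e-6)
    stop(sprintf("water balance violated: relative residual %.3g", rel))

  structure(list(theta = out$theta, psi = out$psi, et = out$et,
                 runoff = out$runoff, discharge = out$discharge,
                 grid = grid, params = params, balance = rel),
            class = "column_state")
}

#' @export
print.column_state <- function(x, ...) {
  cat(sprintf("Soil column state: %d layers x %d days; balance residual %.2g\n",
              nrow(x$psi), ncol(x$psi), x$balance))
  invisible(x)
}
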