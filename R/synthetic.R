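#' Configuration of the synthetic forest community
#'
#' Bundles the knobs of the seeded synthetic-data generator. The defaults are
#' the standard study conditions used throughout the package's tests: a
#' 12-species canopy community observed for 25 years of daily forcing in five
#' 5-year census intervals, a 20-member hydrological ensemble, and growth
#' noise at 25% of the per-species growth signal standard deviation.
#'
#' @param n_species number of species (>= 1).
#' @param n_years calendar years of daily forcing (365-day years, no leap days).
#' @param census_interval_years census interval length, years.
#' @param n_realizations hydrological ensemble size.
#' @param growth_noise_sd growth noise SD; in cm yr-1 when
#'   `growth_noise_relative` is `FALSE`, otherwise as a fraction of each
#'   species' noiseless growth-signal SD.
#' @param growth_noise_relative interpret `growth_noise_sd` as relative.
#' @param tree_noise_sd SD of tree-level growth deviations around the species
#'   mean, cm yr-1 (drives the per-tree census trajectories).
#' @param drought_year_prob probability that a year is an extreme drought year.
#' @param drought_rain_factor rainfall multiplier in drought years.
#' @param drought_vpd_factor VPD multiplier in drought years.
#' @param ensemble_jitter half-width (relative) of the box around the true
#'   soil parameters from which ensemble members are drawn; emulates the
#'   spread of a calibrated best-fit ensemble.
#' @param spinup_years years of spin-up for the soil column (first year of
#'   forcing recycled; the recorded fields cover all `n_years`).
#' @param seed integer seed; identical configs generate identical data.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 12, n_years = 25,
                         census_interval_years = 5, n_realizations = 20,
                         growth_noise_sd = 0.25, growth_noise_relative = TRUE,
                         tree_noise_sd = 0.05,
                         drought_year_prob = 0.2, drought_rain_factor = 0.6,
                         drought_vpd_factor = 1.2, ensemble_jitter = 0.05,
                         spinup_years = 5, seed = 1) {
  cfg <- list(n_species = n_species, n_years = n_years,
              census_interval_years = census_interval_years,
              n_realizations = n_realizations,
              growth_noise_sd = growth_noise_sd,
              growth_noise_relative = growth_noise_relative,
              tree_noise_sd = tree_noise_sd,
              drought_year_prob = drought_year_prob,
              drought_rain_factor = drought_rain_factor,
              drought_vpd_factor = drought_vpd_factor,
              ensemble_jitter = ensemble_jitter,
              spinup_years = spinup_years, seed = as.integer(seed))
  counts <- c("n_species", "n_years", "census_interval_years", "n_realizations")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be >= 1")
  if (cfg$drought_year_prob < 0 || cfg$drought_year_prob > 1)
    stop("drought_year_prob must be in [0, 1]")
  if (cfg$growth_noise_sd < 0 || cfg$tree_noise_sd < 0)
    stop("noise SDs must be non-negative")
  class(cfg) <- "synth_config"
  cfg
}

# seasonal weight in [0, 1]: ~0 mid dry season (mid January), 1 mid wet season
season_weight <- function(doy) 0.5 * (1 - cos(2 * pi * (doy - 15) / 365))

#' Generate daily climate forcing with a pronounced dry season
#'
#' Seasonal daily precipitation (wet-season-peaked, ~2630 mm expected annual
#' total in non-drought years) and VPD (dry-season-peaked, ~1.2 kPa dry-season
#' mean) over `n_years` 365-day years. Annual rainfall totals carry mild
#' lognormal year-to-year variability (sigma 0.1). Extreme droughts arrive as
#' episodes of one to three consecutive years (the El Nino pattern of seasonal
#' tropical forests), with each year having `drought_year_prob` of being in an
#' episode. Each drought year is one of two types with distinct depth
#' signatures: a prolonged-dry-season drought (the dry season runs two months
#' into the wet season; rain in that window is strongly suppressed and VPD
#' elevated, stressing shallow layers) or a wet-season drought (rainfall in
#' the recharge season is scaled by `drought_rain_factor`, starving deep
#' percolation). VPD in a drought year is scaled by `drought_vpd_factor`.
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `year`, `doy`, `precip_mm`, `vpd_kpa` and
#'   attribute `drought_years` (integer vector of drought year indices).
#' @export
gen_forcing <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  n_days <- config$n_years * 365L
  year <- rep(seq_len(config$n_years), each = 365L)
  doy <- rep(seq_len(365L), config$n_years)
  s <- season_weight(doy)
  mean_p <- 1.4 + 11.6 * s              # mm d-1; annual total ~2630 mm, ~42 mm per driest month
  p_wet <- 0.15 + 0.75 * s              # rain-day probability
  rain_day <- stats::rbinom(n_days, 1, p_wet)
  amount <- stats::rexp(n_days, rate = p_wet / mean_p)
  annual_mult <- exp(stats::rnorm(config$n_years, 0, 0.1))
  precip <- rain_day * amount * annual_mult[year]
  vpd <- (0.35 + 0.85 * (1 - s)) * exp(stats::rnorm(n_days, 0, 0.15))
  # drought episodes: starts drawn so the long-run fraction of drought years
  # matches drought_year_prob; episode length 1-3 years
  mean_len <- 2
  drought <- logical(config$n_years)
  y <- 1
  while (y <= config$n_years) {
    if (stats::runif(1) < config$drought_year_prob / mean_len) {
      len <- sample(1:3, 1)
      drought[y:min(config$n_years, y + len - 1)] <- TRUE
      y <- y + len
    } else y <- y + 1
  }
  drought <- which(drought)
  dtype <- sample(c("dry-season", "wet-season"), length(drought), replace = TRUE)
  dry_years <- drought[dtype == "dry-season"]
  wet_years <- drought[dtype == "wet-season"]
  extended_dry <- (year %in% dry_years) & doy > 120 & doy <= 181
  recharge_fail <- (year %in% wet_years) & doy > 181 & doy <= 348
  precip[extended_dry] <- precip[extended_dry] * 0.2
  precip[recharge_fail] <- precip[recharge_fail] * config$drought_rain_factor
  in_drought <- year %in% drought
  vpd[in_drought] <- vpd[in_drought] * config$drought_vpd_factor
  out <- data.frame(year = year, doy = doy, precip_mm = precip, vpd_kpa = vpd)
  attr(out, "drought_years") <- drought
  attr(out, "drought_types") <- dtype
  out
}

#' Generate a synthetic species table with trait-linked vulnerability curves
#'
#' Draws wood specific gravity WSG ~ U(0.35, 0.75) g cm-3 and leaf mass per
#' area LMA ~ U(60, 180) g m-2; sets the vulnerability decline rate B from the
#' trait polynomial [predict_B()] plus Normal noise (`b_noise_sd`), and the
#' conductance scale A from [predict_A()]. True effective rooting depths are
#' assigned to span the 0.21-7.8 m portion of the soil grid (the depth range
#' canopy-tree rooting plausibly occupies; the 13 m layer and the
#' millimetre-scale surface layers are excluded as true depths). Leaf habits
#' alternate evergreen/deciduous; evergreen species get a steeper
#' mortality-exposure slope.
#'
#' @param config a [synth_config()].
#' @param grid a [soil_grid()].
#' @param b_noise_sd SD of the noise added to the trait-predicted B.
#' @return data.frame: `species`, `wsg`, `lma`, `habit`, `max_height_m`,
#'   `erd_true_layer` (grid index), `erd_true_m`, `A`, `B`, `beta0`, `beta1`,
#'   `mort_annual_p` (baseline annual death probability), `mort_slope`
#'   (logit-scale slope on exposure %).
#' @export
gen_species <- function(config, grid = soil_grid(), b_noise_sd = 0.2) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  n <- config$n_species
  sp <- sprintf("sp%02d", seq_len(n))
  wsg <- stats::runif(n, 0.35, 0.75)
  lma <- stats::runif(n, 60, 180)
  B <- predict_B(wsg, lma) + stats::rnorm(n, 0, b_noise_sd)
  if (any(B <= 0)) stop("synthetic species drew a non-positive B; widen trait ranges")
  A <- predict_A(B, lma)
  if (any(A <= 0)) stop("synthetic species drew a non-positive A; widen trait ranges")
  candidate <- which(grid$z >= 0.21 & grid$z <= 7.8)
  layer <- sample(rep(candidate, length.out = n))
  habit <- rep(c("evergreen", "deciduous"), length.out = n)
  data.frame(
    species = sp, wsg = wsg, lma = lma, habit = habit,
    max_height_m = stats::runif(n, 32, 45),
    erd_true_layer = layer, erd_true_m = grid$z[layer],
    A = A, B = B,
    beta0 = stats::runif(n, 0.05, 0.2),
    beta1 = stats::runif(n, 0.2, 0.5),
    mort_annual_p = 0.02,
    mort_slope = ifelse(habit == "evergreen", 0.04, 0.005),
    stringsAsFactors = FALSE
  )
}

#' Generate census-interval growth and per-tree diameter trajectories
#'
#' Forward version of the inverse growth model: species growth in census
#' interval t is \eqn{G_{s,t} = \beta_0 + \beta_1 \bar{F}_{s,t} + N(0, \sigma)}
#' where \eqn{\bar{F}_{s,t}} is the interval mean of the standardized daily
#' product FLC* x VPD^* evaluated at the species' true rooting-depth layer.
#' Per-tree diameter trajectories are built by integrating the species growth
#' plus tree-level noise so the census-processing stage has realistic input.
#'
#' @param species table from [gen_species()].
#' @param factors array species x depth x interval of interval-mean growth
#'   factors (from [interval_factor_array()] on the truth water potentials).
#' @param config a [synth_config()].
#' @param trees_per_species number of trees per species (recycled).
#' @param start_year calendar year of the first census.
#' @return List: `species_growth` (data.frame `species`, `interval`, `G`,
#'   `G_noiseless`), `census` (data.frame `tree_id`, `species`, `dbh_cm`,
#'   `date`, `status`).
#' @export
gen_growth <- function(species, factors, config, trees_per_species = 8,
                       start_year = 1990) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 303L)
  n_sp <- nrow(species)
  n_int <- dim(factors)[3]
  if (dim(factors)[1] != n_sp) stop("factor array does not match species table")
  rows <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    f <- factors[i, species$erd_true_layer[i], ]
    if (any(!is.finite(f)))
      stop("missing growth factor at the true layer for ", species$species[i])
    g0 <- species$beta0[i] + species$beta1[i] * f
    sd_i <- if (config$growth_noise_relative)
      config$growth_noise_sd * stats::sd(g0) else config$growth_noise_sd
    g <- g0 + stats::rnorm(n_int, 0, sd_i)
    rows[[i]] <- data.frame(species = species$species[i],
                            interval = seq_len(n_int),
                            G = g, G_noiseless = g0,
                            stringsAsFactors = FALSE)
  }
  species_growth <- do.call(rbind, rows)

  nt <- rep_len(trees_per_species, n_sp)
  d <- config$census_interval_years
  dates <- start_year + d * (0:n_int)
  census <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    gi <- species_growth$G[species_growth$species == species$species[i]]
    dbh0 <- stats::runif(nt[i], 32, 70)
    for (j in seq_len(nt[i])) {
      gr <- gi + stats::rnorm(n_int, 0, config$tree_noise_sd)
      dbh <- cumsum(c(dbh0[j], gr * d))
      census[[length(census) + 1]] <- data.frame(
        tree_id = sprintf("%s_t%02d", species$species[i], j),
        species = species$species[i],
        dbh_cm = dbh, date = dates, status = "alive",
        stringsAsFactors = FALSE)
    }
  }
  list(species_growth = species_growth,
       census = do.call(rbind, census[!vapply(census, is.null, logical(1))]))
}

#' Generate census mortality counts linked to water-stress exposure
#'
#' Deaths per species and interval are Binomial(N, p) with
#' \eqn{\mathrm{logit}(p) = \mathrm{logit}(1 - (1 - p_{ann})^d) + slope \times exposure},
#' i.e. a baseline annual death probability compounded over the interval and
#' shifted on the logit scale by the species' exposure (% of days beyond its
#' critical threshold). Evergreen species carry a steeper exposure slope than
#' deciduous ones by default, so the evergreen/deciduous contrast in
#' ERD-mortality regressions is reproducible.
#'
#' @param species table from [gen_species()].
#' @param exposure data.frame `species`, `interval`, `exposure_pct` in [0, 100].
#' @param config a [synth_config()].
#' @param n_trees trees at risk per species-interval (recycled over species).
#' @return data.frame `species`, `interval`, `N`, `D`, `d_years`, `exposure_pct`.
#' @export
gen_mortality <- function(species, exposure, config, n_trees = 150) {
  stopifnot(inherits(config, "synth_config"))
  if (any(exposure$exposure_pct < 0 | exposure$exposure_pct > 100))
    stop("exposure must be in [0, 100]")
  set.seed(config$seed + 404L)
  d <- config$census_interval_years
  m <- merge(exposure, species[, c("species", "mort_annual_p", "mort_slope")],
             by = "species", sort = FALSE)
  m <- m[order(m$species, m$interval), ]
  p_int <- 1 - (1 - m$mort_annual_p)^d
  p <- stats::plogis(stats::qlogis(p_int) + m$mort_slope * m$exposure_pct)
  m$N <- rep_len(n_trees, nrow(m))
  m$D <- stats::rbinom(nrow(m), m$N, p)
  m$d_years <- d
  m[, c("species", "interval", "N", "D", "d_years", "exposure_pct")]
}

#' Monotone depth-to-isotope map of soil water
#'
#' \deqn{\delta^2 H(z) = \delta_{deep} + (\delta_{surface} - \delta_{deep})
#'   e^{-z/z_{scale}}}
#' Noise-free values strictly increase toward the surface (evaporative
#' enrichment of shallow soil water).
#'
#' @param z depth, m (>= 0).
#' @param delta_surface per-mil value at the surface.
#' @param delta_deep per-mil deep-water asymptote.
#' @param z_scale e-folding depth of the profile, m.
#' @return delta-2H, per mil.
#' @export
isotope_depth_map <- function(z, delta_surface = -20, delta_deep = -55,
                              z_scale = 2) {
  delta_deep + (delta_surface - delta_deep) * exp(-z / z_scale)
}

#' Generate xylem-water isotope records at the true rooting depths
#'
#' @param species table from [gen_species()].
#' @param noise_sd per-mil SD of measurement noise.
#' @param seed integer seed.
#' @param ... passed to [isotope_depth_map()].
#' @return data.frame `species`, `d2h_xylem`, `se` (per mil).
#' @export
gen_isotopes <- function(species, noise_sd = 1.5, seed = 1, ...) {
  set.seed(as.integer(seed) + 505L)
  d2h <- isotope_depth_map(species$erd_true_m, ...) +
    stats::rnorm(nrow(species), 0, noise_sd)
  data.frame(species = species$species, d2h_xylem = d2h,
             se = rep(noise_sd, nrow(species)), stringsAsFactors = FALSE)
}

#' Generate a hydrological ensemble around a known parameter set
#'
#' Emulates a calibrated best-fit ensemble: `n_realizations` soil parameter
#' sets are Latin-Hypercube sampled from a box of +/- `ensemble_jitter`
#' (relative) around the true parameters, and the water balance is run for
#' each. Full prior-range calibration is provided separately by [calibrate()];
#' this generator stands in for its *output* so the inversion can be exercised
#' at study scale.
#'
#' @param config a [synth_config()].
#' @param params_truth a [soil_params()] vector.
#' @param forcing daily forcing from [gen_forcing()].
#' @param grid a [soil_grid()].
#' @return A `wp_ensemble` (objectives `NA`: members are not scored).
#' @export
gen_ensemble <- function(config, params_truth, forcing, grid = soil_grid()) {
  stopifnot(inherits(config, "synth_config"))
  validate_soil_params(params_truth)
  j <- config$ensemble_jitter
  lo <- pmin(params_truth * (1 - j), params_truth * (1 + j))
  hi <- pmax(params_truth * (1 - j), params_truth * (1 + j))
  ranges <- data.frame(param = names(params_truth), lo = as.numeric(lo),
                       hi = as.numeric(hi), stringsAsFactors = FALSE)
  draws <- lhs_sample(config$n_realizations, ranges, seed = config$seed + 606L)
  n_day <- nrow(forcing)
  psi <- array(NA_real_, dim = c(config$n_realizations, length(grid$z), n_day))
  for (r in seq_len(config$n_realizations)) {
    p <- as_soil_params(draws[r, ])
    psi[r, , ] <- run_column(p, forcing, grid,
                             spinup_years = config$spinup_years)$psi
  }
  structure(list(psi = psi, params = draws,
                 objective = rep(NA_real_, config$n_realizations),
                 grid = grid), class = "wp_ensemble")
}

#' Generate a complete synthetic study
#'
#' Orchestrates the full forward model: climate forcing, the truth soil-water
#' run, species with trait-linked vulnerability curves, seasonal LAI curves,
#' growth and census tables generated from the truth growth factors at each
#' species' true rooting depth, the hydrological ensemble, isotope records,
#' and the census-interval day index.
#'
#' @param config a [synth_config()].
#' @param params_truth true soil parameters (default [soil_params()]).
#' @param grid a [soil_grid()].
#' @return List with elements `config`, `grid`, `forcing`, `truth_state`,
#'   `species`, `curves` (named list of [vulnerability_curve()]), `lai`
#'   (species x day matrix in [0,1]), `vpd_hat`, `intervals` (day index),
#'   `factors_truth`, `growth`, `census`, `ensemble`, `isotopes`.
#' @export
synth_community <- function(config = synth_config(),
                            params_truth = soil_params(),
                            grid = soil_grid()) {
  forcing <- gen_forcing(config)
  truth_state <- run_column(params_truth, forcing, grid,
                            spinup_years = config$spinup_years)
  species <- gen_species(config, grid)
  curves <- lapply(seq_len(nrow(species)), function(i)
    vulnerability_curve(species$A[i], species$B[i], source = "trait-predicted"))
  names(curves) <- species$species

  # seasonal LAI: deciduous species shed leaves in the dry season with
  # species-specific phenological timing; evergreen dips are small enough
  # that day-to-day variability dominates their standardized curve
  set.seed(config$seed + 707L)
  dep <- ifelse(species$habit == "evergreen", 0.05, 0.7)
  shift <- round(stats::runif(nrow(species), -45, 45))
  lai <- t(vapply(seq_len(nrow(species)), function(i) {
    s_dry <- 1 - season_weight((forcing$doy + shift[i] - 1) %% 365 + 1)
    standardize01(1 - dep[i] * s_dry + stats::rnorm(nrow(forcing), 0, 0.03))
  }, numeric(nrow(forcing))))
  rownames(lai) <- species$species

  vpd_hat <- gpp_vpd_proxy(forcing$vpd_kpa)
  intervals <- census_intervals(config$n_years, config$census_interval_years)
  factors_truth <- interval_factor_array(truth_state$psi, curves, vpd_hat,
                                         intervals, structure = "main")
  growth <- gen_growth(species, factors_truth, config)
  ensemble <- gen_ensemble(config, params_truth, forcing, grid)
  isotopes <- gen_isotopes(species, seed = config$seed)

  list(config = config, grid = grid, forcing = forcing,
       truth_state = truth_state, species = species, curves = curves,
       lai = lai, vpd_hat = vpd_hat, intervals = intervals,
       factors_truth = factors_truth,
       growth = growth$species_growth, census = growth$census,
       ensemble = ensemble, isotopes = isotopes)
}

#' Census-interval index for each day of the analysis period
#'
#' @param n_years analysis years (365-day years).
#' @param census_interval_years interval length in years.
#' @return Integer vector of length `n_years * 365`: interval id per day;
#'   `NA` for trailing days not covered by a full interval.
#' @export
census_intervals <- function(n_years, census_interval_years) {
  n_int <- n_years %/% census_interval_years
  idx <- rep(NA_integer_, n_years * 365)
  full <- seq_len(n_int * census_interval_years * 365)
  idx[full] <- rep(seq_len(n_int), each = census_interval_years * 365)
  idx
}
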