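test_that("default grid is the 13-node exponential column", {
  g <- soil_grid()
  expect_equal(g$z, c(0.01, 0.03, 0.06, 0.12, 0.21, 0.37, 0.62,
                      1, 1.7, 2.9, 4.7, 7.8, 13))
  expect_equal(length(g$interfaces), 14)
  expect_equal(g$interfaces[1], 0)
  expect_equal(sum(g$dz), 15)
  expect_true(all(g$dz > 0))
  expect_error(soil_grid(c(0.1, 0.1)), "strictly increasing")
})

test_that("Campbell retention is exact and monotone", {
  p <- soil_params(psi_sat = -0.005, b = 4)
  expect_equal(retention_psi(p[["theta_sat"]], p), -0.005)
  expect_equal(retention_psi(p[["theta_sat"]] / 2, p), -0.005 * 2^4,
               tolerance = 1e-12)
  th <- seq(0.1, p[["theta_sat"]], length.out = 20)
  expect_true(all(diff(retention_psi(th, p)) > 0))
  expect_error(retention_psi(0, p), "positive")
})

test_that("water balance closes and dry columns only lose water", {
  f <- short_forcing()
  st <- run_column(soil_params(), f, spinup_years = 2)
  expect_lt(st$balance, 1e-6)
  expect_true(all(st$psi <= 0))
  expect_true(all(st$theta <= soil_params()[["theta_sat"]] + 1e-12))

  # zero precipitation: no input, so column storage never increases, and in
  # a single-layer column (no inter-layer exchange) the layer only dries
  f0 <- f
  f0$precip_mm <- 0
  st0 <- run_column(soil_params(), f0)
  storage <- colSums(st0$theta * soil_grid()$dz)
  expect_true(all(diff(storage) <= 1e-12))
  expect_lt(st0$balance, 1e-6)
  st1 <- run_column(soil_params(), f0, grid = soil_grid(z = 0.5, bottom = 1))
  expect_true(all(diff(st1$theta[1, ]) <= 1e-12))

  expect_error(run_column(soil_params(), within(f, precip_mm[1] <- -1)),
               "negative")
})

test_that("single-layer bucket saturates and sheds runoff under heavy rain", {
  g1 <- soil_grid(z = 0.5, bottom = 1)
  f <- data.frame(precip_mm = rep(500, 60), vpd_kpa = rep(0.5, 60))
  p <- soil_params()
  st <- run_column(p, f, grid = g1)
  n <- ncol(st$theta)
  expect_equal(st$theta[1, n], p[["theta_sat"]], tolerance = 1e-9)
  expect_gt(st$runoff[n], 0)
  expect_lt(st$balance, 1e-6)
})

test_that("psi amplitude is non-increasing with depth under seasonal forcing", {
  for (seed in 1:3) {
    f <- gen_forcing(synth_config(n_years = 12, seed = seed))
    st <- run_column(soil_params(), f, spinup_years = 3)
    amp <- apply(st$psi, 1, function(x) {
      m <- matrix(x, ncol = 365, byrow = TRUE)
      mean(apply(m, 1, function(y) diff(range(y))))
    })
    expect_true(all(diff(amp) <= 1e-9),
                info = paste("seed", seed))
  }
})

test_that("LHS sampling stratifies each dimension and is reproducible", {
  r1 <- data.frame(param = "x", lo = 0, hi = 1)
  d <- lhs_sample(4, r1, seed = 3)
  expect_equal(sort(findInterval(d$x, c(0, 0.25, 0.5, 0.75, 1))), 1:4)

  d2 <- lhs_sample(50, seed = 9)
  rng <- soil_param_ranges()
  for (j in seq_len(nrow(rng)))
    expect_true(all(d2[[rng$param[j]]] >= rng$lo[j] &
                      d2[[rng$param[j]]] <= rng$hi[j]))
  expect_identical(d2, lhs_sample(50, seed = 9))
  expect_error(lhs_sample(5, data.frame(param = "x", lo = 1, hi = 0)), "lo < hi")
})

test_that("calibration identifies a perfect-fit member and standardizes streams", {
  f <- short_forcing(n_years = 4)
  draws <- lhs_sample(30, seed = 5)
  truth_i <- 11
  st_true <- run_column(rootdepth:::as_soil_params(draws[truth_i, ]), f)
  obs <- list(obs_stream("vwc", st_true$theta[4, ], extract_vwc(4)),
              obs_stream("et", st_true$et, extract_et()))
  ens <- calibrate(draws, f, obs, k = 5)
  expect_s3_class(ens, "wp_ensemble")
  expect_equal(dim(ens$psi)[1], 5)
  expect_equal(which.min(ens$objective_all), truth_i)
  expect_lt(ens$objective[1], 1e-10)
  expect_true(!is.unsorted(ens$objective))
  expect_error(calibrate(draws, f, obs, k = 31), "exceed")

  # standardization invariance: doubling observed and simulated values
  # of a stream leaves the objective unchanged
  st <- run_column(rootdepth:::as_soil_params(draws[1, ]), f)
  o1 <- calibration_objective(st, list(
    obs_stream("vwc", st_true$theta[4, ], extract_vwc(4))))
  o2 <- calibration_objective(st, list(
    obs_stream("vwc2", 2 * st_true$theta[4, ],
               function(state) 2 * state$theta[4, ])))
  expect_equal(o1, o2, tolerance = 1e-12)

  expect_error(
    calibration_objective(st, list(obs_stream("flat", rep(1, ncol(st$theta)),
                                              extract_vwc(1)))),
    "zero variance")
})

test_that("calibration against an off-grid truth narrows parameter ranges", {
  f <- short_forcing(n_years = 4)
  p_true <- soil_params()  # inside the prior box but not an LHS draw
  st_true <- run_column(p_true, f)
  obs <- list(obs_stream("vwc", st_true$theta[4, ], extract_vwc(4)),
              obs_stream("dis", st_true$discharge, extract_discharge()))
  draws <- lhs_sample(120, seed = 21)
  ens <- calibrate(draws, f, obs, k = 10)
  expect_lt(min(ens$objective), median(ens$objective_all))
  rng <- soil_param_ranges()
  for (j in seq_len(nrow(rng))) {
    r <- range(ens$params[[rng$param[j]]])
    expect_lt(r[2] - r[1], rng$hi[j] - rng$lo[j])
  }
})

test_that("drought flags match a brute-force day-of-year percentile oracle", {
  # constant series: nothing strictly below the percentile
  flat <- flag_droughts(rep(-0.3, 365 * 4))
  expect_equal(sum(flat$flags), 0)

  # one year shifted down by 1 MPa is flagged on every day
  set.seed(8)
  base <- rep(-0.2 - 0.1 * season_weight_test(1:365), 20)
  shifted <- base
  shifted[(5 * 365 + 1):(6 * 365)] <- shifted[(5 * 365 + 1):(6 * 365)] - 1
  fl <- flag_droughts(shifted)
  expect_true(all(fl$flags[6, ]))
  expect_equal(sum(fl$flags), 365)

  # oracle equivalence on random small arrays
  set.seed(99)
  for (rep in 1:50) {
    ny <- sample(3:8, 1)
    x <- rnorm(ny * 365, -0.5, 0.3)
    x <- pmin(x, 0)
    fl <- flag_droughts(x, percentile = 5)
    m <- matrix(x, nrow = ny, ncol = 365, byrow = TRUE)
    oracle <- matrix(FALSE, ny, 365)
    for (d in 1:365) {
      thr <- quantile(m[, d], 0.05, names = FALSE)
      for (y in 1:ny) oracle[y, d] <- m[y, d] < thr
    }
    expect_identical(fl$flags, oracle)
  }

  # per-census-interval counts partition the flags
  fl2 <- flag_droughts(shifted, census_interval_years = 5)
  expect_equal(sum(fl2$interval_counts$n_flagged), sum(fl2$flags))
  expect_error(flag_droughts(rep(-1, 365)), "at least 2 years")
})

test_that("ensemble long-CSV round trip preserves the psi field", {
  f <- short_forcing(n_years = 2)
  cfg <- synth_config(n_years = 2, n_realizations = 2, seed = 4)
  ens <- gen_ensemble(cfg, soil_params(), f)
  tmp <- tempfile(fileext = ".csv")
  write_ensemble_csv(ens, tmp)
  back <- read_ensemble_csv(tmp)
  expect_equal(back$psi, ens$psi, tolerance = 1e-10)
  expect_equal(back$grid$z, ens$grid$z)
  unlink(tmp)
})
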