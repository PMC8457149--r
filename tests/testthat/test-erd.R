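test_that("the GPP-from-VPD proxy evaluates, floors and standardizes", {
  # quadratic 2v - v^2 has its interior maximum at v = 1
  v <- seq(0, 2, by = 0.01)
  raw <- 2 * v - v^2
  out <- gpp_vpd_proxy(v)
  expect_equal(which.max(out), which.max(raw))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # monotone below the vertex
  seg <- gpp_vpd_proxy(seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(seg) > 0))
  # negative raw values floor at zero before standardization
  expect_equal(gpp_vpd_proxy(c(0, 1, 5))[3], 0)
  expect_error(gpp_vpd_proxy(rep(1, 10)), "constant")
})

test_that("growth factors are interval means of the standardized product", {
  cv <- vulnerability_curve(10, 2)
  n <- 20
  intervals <- rep(1:2, each = 10)
  psi <- rep(c(0, -2), 10)
  vpd_hat <- rep(1, n)
  f <- growth_factor(cv, psi, vpd_hat, intervals)
  # FLC* alternates 1/0, half the days product 1 and half 0 -> mean 0.5
  expect_equal(f, c(0.5, 0.5))

  # identity: FLC* == 1 and VPD^* == 1 -> factor 1 (degenerate FLC maps to 1)
  f1 <- growth_factor(cv, rep(-0.3, n), vpd_hat, intervals)
  expect_equal(f1, c(1, 1))

  # additive structure returns both components
  fa <- growth_factor(cv, psi, vpd_hat, intervals, structure = "additive")
  expect_equal(colnames(fa), c("flc", "vpd"))
  expect_equal(unname(fa[, "vpd"]), c(1, 1))

  expect_error(growth_factor(cv, psi[-1], vpd_hat, intervals), "misaligned")
  expect_error(growth_factor(cv, psi, vpd_hat, intervals,
                             structure = "multiplicative-lai"),
               "requires a daily LAI")
})

test_that("depth fitting maximizes R2 with shallow tie-break", {
  depths <- c(0.1, 0.5, 1, 2)
  fac <- rbind(c(0.1, 0.5, 0.2, 0.8, 0.4),
               c(0.2, 0.3, 0.25, 0.5, 0.35),
               c(0.5, 0.5, 0.5, 0.5, 0.5),   # constant factor: R2 = 0
               c(0.15, 0.45, 0.22, 0.75, 0.42))
  g <- 0.2 + 0.4 * fac[2, ]               # noise-free from depth 2
  fit <- fit_depth(g, fac, depths)
  expect_equal(fit$best_depth, 0.5)
  expect_equal(fit$best_r2, 1, tolerance = 1e-12)
  expect_equal(fit$fits$beta0[2], 0.2, tolerance = 1e-10)
  expect_equal(fit$fits$beta1[2], 0.4, tolerance = 1e-10)
  expect_equal(fit$fits$r2[3], 0)

  # R2 equals the squared Pearson correlation (brute-force oracle)
  for (zi in c(1, 2, 4))
    expect_equal(fit$fits$r2[zi], cor(g, fac[zi, ])^2, tolerance = 1e-10)

  # identical factors at two depths: the shallower wins
  fac2 <- fac
  fac2[3, ] <- fac2[2, ]
  fit2 <- fit_depth(0.2 + 0.4 * fac2[2, ], fac2, depths)
  expect_equal(fit2$best_depth, 0.5)

  expect_error(fit_depth(g[1:2], fac[, 1:2], depths), "at least 3")
})

test_that("ERD aggregation is the lower median with SD/sqrt(n) uncertainty", {
  est <- estimate_erd(c(0.37, 0.62, 0.62))
  expect_equal(est$erd, 0.62)
  expect_equal(est$se, sd(c(0.37, 0.62, 0.62)) / sqrt(3))

  est2 <- estimate_erd(rep(1.7, 8))
  expect_equal(est2$se, 0)
  est3 <- estimate_erd(2.9)
  expect_equal(est3$erd, 2.9)
  expect_equal(est3$se, 0)
  # lower median on even counts stays on the grid
  expect_equal(estimate_erd(c(0.37, 0.62))$erd, 0.37)
  expect_error(estimate_erd(numeric(0)), "no realizations")
})

test_that("isotope validation regresses ERD on d2H with a species threshold", {
  erd <- data.frame(species = letters[1:6],
                    erd_m = c(0.21, 0.37, 0.62, 1.7, 2.9, 4.7))
  iso <- data.frame(species = letters[1:6],
                    d2h_xylem = c(-24, -27, -31, -41, -47, -52))
  v <- validate_isotopes(erd, iso)
  expect_equal(v$n, 6)
  expect_gt(v$r2, 0.8)

  # perfectly collinear toy data
  iso2 <- iso
  iso2$d2h_xylem <- -20 - 4 * erd$erd_m
  expect_equal(suppressWarnings(validate_isotopes(erd, iso2))$r2, 1,
               tolerance = 1e-10)

  # permuting a monotone pairing strictly lowers R2
  iso3 <- iso
  set.seed(2)
  iso3$d2h_xylem <- sample(iso$d2h_xylem)
  expect_lt(validate_isotopes(erd, iso3)$r2, v$r2)

  expect_error(validate_isotopes(erd[1:2, ], iso), "at least 3")
})

test_that("zero-noise synthetic growth identifies the true layer exactly", {
  cfg <- synth_config(n_species = 6, n_realizations = 4, seed = 3,
                      growth_noise_sd = 0, tree_noise_sd = 0)
  cm <- synth_community(cfg)
  res <- fit_erd(cm$ensemble, cm$growth, cm$curves, cm$vpd_hat, cm$intervals)
  tab <- merge(res$erd, cm$species[, c("species", "erd_true_m")])
  expect_equal(tab$erd_m, tab$erd_true_m)
})

test_that("structure selection returns a full ranking and trivial cases", {
  cfg <- small_config(seed = 7, growth_noise_sd = 0.05)
  cm <- synth_community(cfg)
  # validate against all species: the deep-subset cutoff can leave too few
  # overlaps in a 6-species toy community
  sel <- suppressWarnings(select_structure(cm, d2h_max = NULL))
  expect_equal(nrow(sel$ranking), 3)
  expect_true(sel$best %in% sel$ranking$structure)
  expect_equal(sel$ranking$r2, sort(sel$ranking$r2, decreasing = TRUE))

  one <- select_structure(cm, structures = "main", d2h_max = NULL)
  expect_equal(one$best, "main")
  expect_equal(nrow(one$ranking), 1)
})
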