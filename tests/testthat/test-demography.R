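test_that("mortality rate formula is exact with validated inputs", {
  expect_equal(mortality_rate(100, 10, 5), 2)
  expect_equal(mortality_rate(100, 0, 5), 0)
  expect_equal(mortality_rate(1, 1, 1), 100)
  expect_equal(mortality_rate(c(100, 50), c(10, 5), 5), c(2, 2))
  expect_error(mortality_rate(0, 0, 5), "N < 1")
  expect_error(mortality_rate(10, 11, 5), "D <= N")
  expect_error(mortality_rate(10, 1, 0), "positive")
})

test_that("exposure counts strictly-below days as a percentage", {
  expect_equal(exposure_fraction(rep(-1, 100), -0.5), 100)
  expect_equal(exposure_fraction(rep(-0.1, 100), -0.5), 0)
  expect_equal(exposure_fraction(rep(c(-1, -0.1), 50), -0.5), 50)
  # boundary days do not count
  expect_equal(exposure_fraction(rep(-0.5, 10), -0.5), 0)
  expect_error(exposure_fraction(numeric(0), -0.5), "empty")
  expect_error(exposure_fraction(-1, 0.5), "negative")
})

test_that("exposure declines with depth: mechanism and standard climatology", {
  # mechanism: on a climatology that is pointwise wetter at deeper layers,
  # exposure at a fixed threshold is non-increasing with depth
  set.seed(77)
  z <- soil_grid()$z
  a <- 0.8 * (1 + sin(2 * pi * (1:(365 * 4)) / 365)) / 2 +
    abs(rnorm(365 * 4, 0, 0.2))
  psi_toy <- -outer(exp(-z / 2), a)  # layers x days, ordered by construction
  for (crit in c(-0.02, -0.1, -0.3)) {
    expo <- apply(psi_toy, 1, exposure_fraction, psi_crit = crit)
    expect_true(all(diff(expo) <= 1e-9), info = paste("crit", crit))
  }

  # standard synthetic climatology: species exposure at their rooting-depth
  # layer (species-specific thresholds) declines with rooting depth
  cfg <- small_config(seed = 4)
  cm <- synth_community(cfg)
  mean_psi <- ensemble_mean_psi(cm$ensemble)
  crit_sp <- vapply(cm$curves, psi_at_loss, numeric(1), f = 0.2)
  erd_true <- data.frame(species = cm$species$species,
                         erd_m = cm$species$erd_true_m)
  et <- exposure_table(cm$ensemble, erd_true, crit_sp, cm$intervals)
  agg <- aggregate(exposure_pct ~ species, et, mean)
  agg <- merge(agg, erd_true)
  expect_lt(cor(agg$erd_m, agg$exposure_pct, method = "spearman"), 0)
  expect_lt(agg$exposure_pct[which.max(agg$erd_m)],
            agg$exposure_pct[which.min(agg$erd_m)])
  expect_lt(mean(agg$exposure_pct[agg$erd_m >= 1.7]),
            mean(agg$exposure_pct[agg$erd_m < 1.7]))

  # the exposure_table agrees with direct counting for one species
  erd <- data.frame(species = cm$species$species[1], erd_m = 0.62)
  crit <- c(-0.3)
  names(crit) <- cm$species$species[1]
  et <- exposure_table(cm$ensemble, erd, crit, cm$intervals)
  layer <- match(0.62, cm$grid$z)
  days <- which(cm$intervals == 1)
  expect_equal(et$exposure_pct[et$interval == 1],
               100 * mean(mean_psi[layer, days] < -0.3))

  # per-realization averaging stays in [0, 100] and differs in general
  et2 <- exposure_table(cm$ensemble, erd, crit, cm$intervals,
                        method = "mean-exposure")
  expect_true(all(et2$exposure_pct >= 0 & et2$exposure_pct <= 100))
})

test_that("mortality regressions match a closed-form OLS oracle", {
  erd <- data.frame(species = letters[1:5], erd_m = c(0.2, 0.6, 1, 2.9, 4.7))
  habits <- data.frame(species = letters[1:5], habit = "evergreen")
  mort <- data.frame(species = letters[1:5], interval = 1,
                     M = c(3.1, 2.2, 2.0, 1.1, 0.6))
  out <- erd_mortality_regression(mort, erd, habits)
  oracle <- ols_oracle(erd$erd_m, mort$M)
  expect_equal(out$slope, oracle$b1, tolerance = 1e-10)
  expect_equal(out$r2, oracle$r2, tolerance = 1e-10)

  # perfectly linear: R2 = 1; constant: R2 = 0
  mort$M <- 4 - 0.5 * erd$erd_m
  expect_equal(suppressWarnings(erd_mortality_regression(mort, erd, habits)$r2),
               1, tolerance = 1e-10)
  mort$M <- 2
  expect_equal(suppressWarnings(erd_mortality_regression(mort, erd, habits)$r2),
               0, tolerance = 1e-10)

  # groups below the species threshold are skipped with a message
  habits2 <- data.frame(species = letters[1:5],
                        habit = c("evergreen", "evergreen", "brevideciduous",
                                  "obligate deciduous", "evergreen"))
  mort$M <- c(3, 2, 2, 1, 0.5)
  expect_message(out2 <- erd_mortality_regression(mort, erd, habits2),
                 "skipping deciduous")
  expect_equal(out2$group, "evergreen")
  expect_equal(out2$n, 3)
})

test_that("evergreen mortality tracks ERD more tightly than deciduous", {
  # the evergreen exposure slope exceeds the deciduous one by construction,
  # so in expectation over seeds the evergreen R2 is larger
  r2e <- r2d <- numeric(20)
  for (s in 1:20) {
    cfg <- synth_config(seed = s)
    set.seed(s + 1000)
    sp <- gen_species(cfg)
    # synthetic climatology: exposure declines with rooting depth
    expos <- data.frame(species = sp$species, interval = 1,
                        exposure_pct = pmax(0, 90 - 12 * sp$erd_true_m) +
                          rnorm(nrow(sp), 0, 3))
    expos$exposure_pct <- pmin(100, pmax(0, expos$exposure_pct))
    m <- gen_mortality(sp, expos, cfg, n_trees = 400)
    erd <- data.frame(species = sp$species, erd_m = sp$erd_true_m)
    reg <- erd_mortality_regression(m, erd, sp[, c("species", "habit")])
    r2e[s] <- reg$r2[reg$group == "evergreen"]
    r2d[s] <- reg$r2[reg$group == "deciduous"]
  }
  expect_gt(mean(r2e), mean(r2d))
  expect_gt(mean(r2e > r2d), 0.5)
})

test_that("trait correlations are exact Spearman with midranks and thresholds", {
  erd <- data.frame(species = letters[1:7], erd_m = c(0.2, 0.4, 0.6, 1, 1.7, 2.9, 4.7))
  tr <- data.frame(species = letters[1:7],
                   kmax_stem = c(0.5, 0.9, 1.2, 1.8, 2.5, 3.1, 4.0),
                   psi_tlp = -c(2.4, 2.1, 1.9, 1.6, 1.5, 1.3, 1.1),
                   psi88_stem = -c(6, 5.2, 4.4, 3.9, 3.1, 2.6, 2.2),
                   safety_margin = c(3.2, 2.8, 2.5, 2.1, 1.6, 1.2, 0.9))
  out <- erd_trait_correlation(erd, tr)
  expect_equal(out$rho[out$trait == "kmax_stem"], 1)
  expect_equal(out$rho[out$trait == "safety_margin"], -1)

  # brute-force rank formula oracle on a permuted 7-point set
  set.seed(14)
  tr2 <- tr
  tr2$kmax_stem <- sample(tr$kmax_stem)
  out2 <- erd_trait_correlation(erd, tr2)
  expect_equal(out2$rho[out2$trait == "kmax_stem"],
               spearman_oracle(erd$erd_m, tr2$kmax_stem), tolerance = 1e-10)

  # below the species threshold the trait is skipped
  tr3 <- tr
  tr3$kmax_stem[4:7] <- NA
  expect_message(out3 <- erd_trait_correlation(erd, tr3), "skipping trait")
  expect_false("kmax_stem" %in% out3$trait)
})
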