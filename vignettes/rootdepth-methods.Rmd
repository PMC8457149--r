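---
title: "Inverse estimation of effective rooting depth: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse estimation of effective rooting depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootdepth)
```

## The problem

How deep do canopy trees draw their water? Direct observation of rooting
depth is essentially impossible at the community scale in species-rich
tropical forests, yet depth of water access is a first-order control on
which trees survive a drought. `rootdepth` implements an *inverse* approach:
a species' **effective rooting depth (ERD)** is the soil depth whose daily
water-potential dynamics, passed through the species' leaf hydraulic
vulnerability curve, best explain its multi-decadal census-interval diameter
growth. ERD is a central tendency of water uptake, not a maximum rooting
depth, and — because the soil column is one-dimensional — it is best read as
a *relative* ordering among co-occurring species rather than an absolute
depth.

The pipeline has five stages, each an exported module of the package and a
numbered driver under `analysis/`:

1. **Synthetic study generator** (`synth_config()`, `synth_community()` and
   the `gen_*()` functions): the forward version of every model below, so
   the whole chain is testable without field data.
2. **Soil water** (`run_column()`, `lhs_sample()`, `calibrate()`,
   `flag_droughts()`): a daily multi-layer water balance, Latin-Hypercube
   ensemble calibration against observation streams, and a day-of-year
   percentile drought climatology.
3. **Leaf hydraulics** (`fit_vulnerability()`, `predict_B()`, `predict_A()`,
   `flc()`, `psi_at_loss()`): exponential vulnerability curves, fitted or
   trait-predicted.
4. **Growth processing and the inversion** (`annual_growth()`,
   `filter_trees()`, `species_series()`, `growth_factor()`, `fit_depth()`,
   `estimate_erd()`, `validate_isotopes()`, `select_structure()`).
5. **Demography** (`mortality_rate()`, `exposure_table()`,
   `erd_mortality_regression()`, `erd_trait_correlation()`).

## The growth model and its inversion

Leaf hydraulic conductance declines with water potential as
\(K_{leaf}(\Psi) = A\,e^{-B|\Psi|}\); its normalized form, the fractional
leaf conductance \(FLC(\Psi) = e^{-B|\Psi|}\in(0,1]\), proxies stomatal
limitation. Because pre-dawn leaf water potential approaches soil water
potential, \(\Psi_{soil}\) at a depth \(z\) can stand in for
\(\Psi_{leaf}\). The growth model for species \(s\) in census interval
\(t\), conditional on a depth \(z\), is

\[ G_{s,t|z} = \beta_0 + \beta_1 \frac{1}{n_t}\sum_{i\in t}
   FLC^{*}_{s,i|z} \cdot \widehat{VPD}^{*}_{i} + \epsilon, \]

where \(\widehat{VPD}\) is a polynomial GPP proxy of vapor pressure deficit
(rising to an interior maximum, then falling as stomata close), and \(*\)
marks standardization to \([0,1]\) over the full analysis period (within
species for FLC). The inversion fits this regression at every depth of the
soil grid and every hydrological realization; the best depth maximizes
\(R^2\) (ties to the shallower depth), and the species ERD is the median of
best depths across realizations (lower median, so the estimate stays on the
grid), with SE = SD/\(\sqrt{n}\).

Two alternate structures are implemented: *additive* (interval means of
FLC\(^*\) and \(\widehat{VPD}^*\) as separate regressors) and
*multiplicative-LAI* (the product additionally scaled by a standardized
seasonal leaf-area-index curve). `select_structure()` ranks structures by
how well their ERD estimates explain xylem-water \(\delta^2\)H — a
nonfractionating tracer of water-uptake depth — and breaks ties toward the
candidate listed first (the most parsimonious).

**Why validation uses a deep subset.** Soil-water \(\delta^2\)H saturates
toward its deep asymptote, so the ERD–isotope relationship is convex; a
linear \(R^2\) computed over the whole profile can *reward* structures that
distort shallow estimates into a straighter line. Validation therefore drops
species with \(\delta^2\)H above \(-40\) per mil (the steep, ambiguous
shallow end) and uses the deeper, near-linear portion — typically three to
six species.

## The soil water balance

ERD needs daily \(\Psi_{soil}(z,t)\) over the whole column. A full land
surface model is out of scope; the package uses a 9-parameter layered bucket
(`soil_params()`) on the 13-node exponential grid
Z = (0.01, 0.03, 0.06, 0.12, 0.21, 0.37, 0.62, 1, 1.7, 2.9, 4.7, 7.8, 13) m,
with interfaces at midpoints, the top at 0 m and the bottom at 15 m. Water
retention is Campbell's power law \(\Psi = \psi_{sat}(\theta/\theta_{sat})^{-b}\)
and conductivity \(K = K_{sat,0}\,e^{-z/efold}\,adj\,(\theta/\theta_{sat})^{2b+3}\).

The daily step: overnight gravity drainage of water above field capacity
(fluxes from the start-of-day state, so pulses advance one layer per day,
with 30% of each layer's drainage shed laterally as interflow to the
stream); capillary redistribution between adjacent layers (2 mm d\(^{-1}\)
per unit relative-saturation difference, decaying with depth on the
conductivity e-fold); atmospheric demand `et_scalar * VPD` met 30% by
surface evaporation and 70% by root-weighted transpiration
(\(\propto e^{-z/root\_efold}\,dz\)), throttled between 0.5 and 0.25
saturation; then interception and top-down infiltration up to saturation,
capped by surface \(K_{sat}\). The structural constants (residual 0.25,
field capacity 0.55, stress ramp 0.25–0.5 of saturation, 30% evaporation and
interflow shares, redistribution 2 mm d\(^{-1}\)) are fixed, documented
constants, not calibration parameters. The daily balance closes exactly by
construction and every run asserts a relative residual below 1e-6.

This structure was chosen so the simulated column reproduces the
qualitative hydrology of a seasonally wet tropical forest on clay soils:
topsoil that saturates on rain days and dries to roughly \(-1\) MPa through
the dry season; water potential below about 1.7 m never more negative than
\(-0.5\) MPa; annual recharge of the deep column; and a seasonal
\(\Psi\) amplitude that decays monotonically with depth — the structural
assumption the inversion exploits. The retention scale (b = 5,
\(\psi_{sat} = -0.001\) MPa) additionally places the deep layers' resident
potentials above the trait-implied \(\Psi_{20}\) band of the community
(\(-0.02\) to \(-0.07\) MPa), so deep-rooted species' exposure to stress
collapses with depth, as observed in such forests.

**Calibration** scores each Latin-Hypercube parameter draw by the mean over
observation streams of RMSE divided by the stream's standard deviation
(equal weighting), and keeps the *k* best members as the water-potential
ensemble (the field-scale workflow is 5000 draws, top 100; the packaged
tests use 500/20). `lhs_sample()` guarantees one draw per equal-probability
stratum per dimension. **Drought climatology**: a day is an extreme
hydrological drought at a depth when the realization-mean \(\Psi\) is
strictly more negative than the 5th percentile of that day-of-year's values
pooled across years.

**Spin-up.** The first simulated year is recycled (`spinup_years`, default 5
in the generator) before recording starts, so the recorded field covers the
full analysis window and all five census intervals while still starting from
a relaxed state; the balance is checked over the recorded window.

## The synthetic study and what it does (not) emulate

The generator's defaults are the standard study conditions used by the
tests: 12 species, 25 years of daily forcing, five 5-year census intervals,
a 20-member hydrological ensemble, growth noise at 25% of each species'
growth-signal SD.

* **Climate**: 365-day years; rainfall ~2630 mm yr\(^{-1}\) with a
  December–April dry season (~40 mm in the driest month) and lognormal
  annual variability (sigma 0.1); VPD peaks in the dry season (~1.2 kPa).
  Extreme droughts arrive as 1–3-year episodes at a 20% per-year rate, in
  two types with distinct depth signatures: *prolonged-dry-season* droughts
  (the dry season runs two months into the wet season) and *wet-season*
  droughts (recharge rainfall scaled by 0.6). The two types are what make
  depth identifiable from only five interval means: they load shallow
  drying and deep recharge failure onto different intervals.
* **Species**: WSG ~ U(0.35, 0.75) g cm\(^{-3}\), LMA ~ U(60, 180)
  g m\(^{-2}\) — the canopy-tree trait range over which the vulnerability
  polynomials stay positive; B from the trait polynomial plus N(0, 0.2)
  noise; true ERD layers span 0.21–7.8 m (the depth band canopy rooting
  plausibly occupies; the 13 m layer and millimetre-scale surface layers
  are excluded as truths). Alternating evergreen/deciduous habits.
* **Ensemble**: `gen_ensemble()` emulates a *calibrated* ensemble by
  Latin-Hypercube sampling a ±5% box around the true soil parameters. The
  width is pinned by the zero-noise identifiability requirement (with
  noise-free growth, every species must recover its true layer exactly);
  a ±10% spread already breaks that, i.e. it is wider than any ensemble
  that had genuinely been calibrated against soil moisture by depth.
  Full prior-range calibration is a separate, separately-tested stage.
* **Mortality**: deaths are Binomial with
  logit\(p\) = logit\((1-(1-p_{ann})^d)\) + slope × exposure, baseline
  \(p_{ann}\) = 2% yr\(^{-1}\); the evergreen exposure slope (0.04 per
  exposure-%) exceeds the deciduous one (0.005), encoding the hypothesis
  that deciduous species escape drought by shedding leaves. The logistic
  link keeps probabilities valid; the field analysis is a linear
  regression of rate on ERD, and no generative model is claimed for the
  real forest.
* **Isotopes**: \(\delta^2H(z) = -55 + 35\,e^{-z/2}\) per mil plus N(0, 1.5)
  noise, evaluated at the species' true ERD — a monotone stand-in for the
  soil profile, not isotope physics.

What passing tests do **not** show about real data: the generator draws
growth noise i.i.d. across intervals (real census errors are autocorrelated
and size-dependent), its species share one growth functional form, its
soil column is horizontally homogeneous, and its isotope map is exact up to
white noise. Recovery rates measured here are upper bounds on what the
method could achieve in the field.

## Numerical and procedural choices

* **Vulnerability fits** initialize from the closed-form log-linear
  regression of \(\ln K\) on \(|\Psi|\) (exact on noise-free data) and
  refine by `nls` when it converges; whether the original analysis fitted
  on the log or natural scale is unstated, and the two agree at low noise.
  All potentials are stored non-positive and the exponent acts on
  \(|\Psi|\) with B > 0, so conductance declines with drying; species with
  non-positive trait-predicted A or B are flagged and excluded, never
  clamped.
* **Best-depth statistic**: maximum \(R^2\) (equivalently minimum SSE for
  the one-regressor model); ties go to the shallower depth.
* **Degenerate FLC** (a constant series, e.g. at a permanently wet depth)
  standardizes to 1, reducing the factor to VPD scaling.
* **Growth processing**: trees enter at >= 30 cm dbh, species maximum
  height >= 30 m, complete alive records across all censuses, growth
  outliers outside (-0.5, 7.5) cm yr\(^{-1}\) removed (conventional
  large-plot bounds; the original procedure is not public). The size model
  is a pooled per-interval regression of growth on ln(dbh), chosen over
  per-species fits for stability at small n; residuals are z-scored within
  interval and the species value is the median.
  *Known limitation:* within-interval z-scoring removes community-common
  growth variation. In a small synthetic community whose species share one
  response form, that common mode carries most of the depth signal, so the
  inversion is exercised on the generated species series, and the
  processing stage is validated by its own property — per interval, the
  processed values are a monotone transform of the generating growth.
* **Exposure** uses a strict inequality (boundary days do not count) and
  the realization-mean \(\Psi\) by default (`method = "mean-exposure"`
  averages per-realization exposures instead; which the original analysis
  used is unstated). Mortality regressions flag significance at both 0.05
  and 0.1 with no multiple-testing correction, matching the source
  convention; the mortality population is trees >= 10 cm dbh, distinct
  from the >= 30 cm growth population.
* **Problem sizes** in the packaged tests — 500-draw/top-20 calibration on
  8 years of forcing, 20-realization ensembles, 20-seed structure-selection
  and degradation sweeps — are the package's chosen desk-scale study
  conditions; the corresponding field-scale sizes (5000/100, 100
  realizations) are set by two arguments.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
cfg <- synth_config(seed = 1)
cm  <- synth_community(cfg)

# inversion: growth ~ depth-wise factor, per realization, median best depth
res <- fit_erd(cm$ensemble, cm$growth, cm$curves, cm$vpd_hat, cm$intervals)
head(res$erd)

# isotope validation on the deep, near-linear part of the profile
validate_isotopes(res$erd, subset(cm$isotopes, d2h_xylem <= -40))

# demography: exposure beyond psi20 at the ERD layer, mortality regressions
crit <- vapply(cm$curves, psi_at_loss, numeric(1), f = 0.2)
expo <- exposure_table(cm$ensemble, res$erd, crit, cm$intervals)
mort <- gen_mortality(cm$species, expo, cfg)
erd_mortality_regression(mort, res$erd, cm$species[, c("species", "habit")])
```

The numbered scripts under `analysis/` run exactly these stages and write
their tables under `results/`; `scripts/acceptance.R` recomputes the
headline quantities (recovery rates, calibration recovery, oracle checks,
demography statistics) from scratch for a given seed.

## Known limitations

* ERD is a single central-tendency depth; no rooting profiles, stem
  capacitance, or diurnal leaf-water dynamics — species buffering drought
  with stored water will look deeper-rooted than they are.
* The bucket model has no energy balance, snow, aquifer, lateral inflow or
  Richards solver; its fixed structural constants trade realism for
  robustness and mass balance.
* The 1-D column means ERD differences between species are interpretable;
  absolute depths are not.
* Depth identifiability rests on five interval means per species; adjacent
  deep layers (>= 2.9 m) have strongly correlated dynamics and remain the
  dominant confusion mode.
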