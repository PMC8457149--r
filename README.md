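# rootdepth

Inverse estimation of tree **effective rooting depth (ERD)** in seasonal
tropical forests, with the hydrology, hydraulics, and demography around it.

Community-scale rooting depths are unobservable in species-rich forests, yet
depth of water access decides who survives a drought. `rootdepth` estimates,
for each canopy species, the soil depth whose daily water-potential dynamics
best explain its census-interval diameter growth. The growth model for
species *s* in census interval *t*, conditional on depth *z*, is

    G[s,t|z] = b0 + b1 * mean_over_days( FLC*[s,i|z] * VPDhat*[i] ) + e

where `FLC(psi) = exp(-B|psi|)` is the fractional leaf hydraulic conductance
from the species' vulnerability curve `K = A exp(-B|psi|)`, `VPDhat` is a
polynomial GPP proxy of vapor pressure deficit, and `*` marks
standardization to [0, 1] over the analysis period. The regression is fitted
at every depth of a 13-node soil grid (0.01–13 m) and every member of a
calibrated soil-water ensemble; the best depth maximizes R²; the species ERD
is the median best depth across hydrological realizations (± SE).

The package provides:

* a daily multi-layer **soil water balance** (Campbell retention, compiled
  core) with Latin-Hypercube **ensemble calibration** against observation
  streams (soil moisture, discharge, ET) under an equally weighted
  standardized-RMSE objective, and a day-of-year 5th-percentile
  **hydrological drought** climatology;
* **leaf vulnerability curves** fitted from conductance–potential pairs or
  predicted from wood specific gravity and leaf mass per area, with derived
  critical thresholds `psi20`;
* **forest-census growth processing** (size filters, outlier rules, median
  standardized size-model residuals);
* the **depth inversion** itself, with isotope (delta-2H) validation and
  growth-model **structure selection**;
* **demography**: mortality rates `M = (D/N)(100/d)`, % of days beyond
  `psi_crit = psi20` at the rooting-depth layer, ERD–mortality regressions
  by leaf habit, and ERD–trait rank correlations;
* a seeded **synthetic-data generator** implementing the forward version of
  every model above, so the whole pipeline is testable end to end.

## Worked example

```r
library(rootdepth)

cfg <- synth_config(seed = 1)   # 12 species, 25 y daily forcing, 20 realizations
cm  <- synth_community(cfg)

res <- fit_erd(cm$ensemble, cm$growth, cm$curves, cm$vpd_hat, cm$intervals)
merge(res$erd, cm$species[, c("species", "erd_true_m")])
```

```
   species erd_m       se_m erd_true_m
1     sp01 13.00 0.47718473       0.62
2     sp02  0.37 0.00000000       0.37
3     sp03  1.00 0.04817730       1.00
...
10    sp10  4.70 0.16517933       4.70
11    sp11  0.21 0.00000000       0.21
12    sp12  2.90 0.12388450       1.70
```

Ten of twelve species land exactly on their true layer (83%) at growth noise
equal to 25% of the signal SD; with noise-free growth all twelve are exact.
Validating the estimates against xylem-water isotopes on the deep,
near-linear part of the profile:

```r
validate_isotopes(res$erd, subset(cm$isotopes, d2h_xylem <= -40))
#> $r2 0.839  $p 0.263  $n 3
```

Exposure to water stress (% of days the ERD-layer water potential is more
negative than the species' `psi20`) collapses with rooting depth — shallow
species sit near 50%, species at 2.9 m and deeper near 0% (Spearman
rho = -0.86) — and mortality rates regress on ERD far more tightly for
evergreen than for deciduous species, the signature of drought escape by
leaf shedding.

The numbered scripts under `analysis/` (`01_simulate.R` …
`05_demography.R`) run the five stages in order and write their tables
under `results/`.

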