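#' Annualized mortality rate for a census interval
#'
#' \deqn{M = \frac{D}{N} \times \frac{100}{d}} in % yr-1, where `N` trees of
#' the species were alive at the first census, `D` of those were dead by the
#' second, and `d` is the interval duration in years (based on mean census
#' dates). Vectorized; integer inputs give exact rational outputs.
#'
#' @param N trees alive at the first census (>= 1).
#' @param D of those, dead by the second census (0 <= D <= N).
#' @param d interval duration, years (> 0).
#' @return Mortality rate, % yr-1.
#' @export
mortality_rate <- function(N, D, d) {
  if (any(N < 1)) stop("mortality rate undefined for N < 1")
  if (any(D < 0) || any(D > N)) stop("need 0 <= D <= N")
  if (any(d <= 0)) stop("interval duration must be positive")
  (D / N) * (100 / d)
}

#' Percentage of days beyond a critical water-potential threshold
#'
#' The fraction (in %) of days on which the soil water potential is strictly
#' more negative than the species' critical threshold (boundary days do not
#' count).
#'
#' @param psi daily water potential series at the species' rooting-depth
#'   layer, MPa.
#' @param psi_crit critical threshold, MPa (< 0); typically
#'   [psi_at_loss()]`(0.2, curve)`.
#' @return Percentage of days in [0, 100].
#' @export
exposure_fraction <- function(psi, psi_crit) {
  if (length(psi) == 0) stop("empty water potential series")
  if (psi_crit >= 0) stop("psi_crit must be negative")
  100 * mean(psi < psi_crit)
}

#' Per-species, per-interval exposure to water stress
#'
#' For each species, takes the water potential series in the soil layer
#' matching its estimated rooting depth and computes the percentage of days in
#' each census interval beyond its critical threshold. By default the
#' realization-mean water potential is used; alternatively the per-realization
#' exposures are averaged.
#'
#' @param ensemble a `wp_ensemble`.
#' @param erd data.frame `species`, `erd_m` (grid depths).
#' @param psi_crit named vector of critical thresholds (MPa) per species.
#' @param intervals day-to-interval index ([census_intervals()]).
#' @param method `"mean-psi"` (exposure of the realization-mean series) or
#'   `"mean-exposure"` (mean of per-realization exposures).
#' @return data.frame `species`, `interval`, `exposure_pct`.
#' @export
exposure_table <- function(ensemble, erd, psi_crit, intervals,
                           method = c("mean-psi", "mean-exposure")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "wp_ensemble"))
  ids <- sort(unique(intervals[!is.na(intervals)]))
  mean_psi <- ensemble_mean_psi(ensemble)
  rows <- vector("list", nrow(erd) * length(ids))
  k <- 0
  for (i in seq_len(nrow(erd))) {
    sp <- erd$species[i]
    layer <- match(erd$erd_m[i], ensemble$grid$z)
    if (is.na(layer)) stop("ERD for ", sp, " is not a grid depth")
    crit <- psi_crit[[sp]]
    for (iv in ids) {
      days <- which(!is.na(intervals) & intervals == iv)
      e <- if (method == "mean-psi") {
        exposure_fraction(mean_psi[layer, days], crit)
      } else {
        mean(vapply(seq_len(dim(ensemble$psi)[1]), function(r)
          exposure_fraction(ensemble$psi[r, layer, days], crit), numeric(1)))
      }
      k <- k + 1
      rows[[k]] <- data.frame(species = sp, interval = iv, exposure_pct = e,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Regress mortality rates on rooting depth by leaf-habit group and interval
#'
#' All deciduous leaf habits are pooled into one group; per census interval
#' and group with at least `min_species` species, mortality rate is regressed
#' on ERD by OLS. Significance is flagged at alpha = 0.05 and alpha = 0.1
#' without multiple-testing correction.
#'
#' @param mortality data.frame `species`, `interval`, `M` (% yr-1); or with
#'   columns `N`, `D`, `d_years` from which `M` is computed.
#' @param erd data.frame `species`, `erd_m`.
#' @param habits data.frame `species`, `habit` (`"evergreen"` vs any
#'   deciduous label).
#' @param min_species minimum species per group-interval.
#' @return data.frame `interval`, `group`, `n`, `slope`, `r2`, `p`,
#'   `sig05`, `sig10`; group-intervals below the species threshold are
#'   skipped with a message.
#' @export
erd_mortality_regression <- function(mortality, erd, habits, min_species = 3) {
  if (!"M" %in% names(mortality))
    mortality$M <- mortality_rate(mortality$N, mortality$D, mortality$d_years)
  habits$group <- ifelse(habits$habit == "evergreen", "evergreen", "deciduous")
  m <- merge(merge(mortality, erd[, c("species", "erd_m")], by = "species"),
             habits[, c("species", "group")], by = "species")
  rows <- list()
  for (iv in sort(unique(m$interval))) {
    for (grp in c("evergreen", "deciduous")) {
      d <- m[m$interval == iv & m$group == grp, ]
      if (nrow(d) < min_species) {
        message("skipping ", grp, " interval ", iv, ": only ", nrow(d), " species")
        next
      }
      if (stats::var(d$erd_m) == 0) {
        message("skipping ", grp, " interval ", iv, ": no ERD variation")
        next
      }
      fit <- stats::lm(M ~ erd_m, data = d)
      s <- summary(fit)
      degenerate <- stats::var(d$M) == 0
      r2 <- if (degenerate) 0 else s$r.squared
      p <- if (degenerate) NA_real_ else s$coefficients["erd_m", "Pr(>|t|)"]
      rows[[length(rows) + 1]] <- data.frame(
        interval = iv, group = grp, n = nrow(d),
        slope = unname(stats::coef(fit)[2]), r2 = r2, p = p,
        sig05 = !is.na(p) && p < 0.05, sig10 = !is.na(p) && p < 0.1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlations between rooting depth and hydraulic traits
#'
#' Rank correlation (midranks on ties) and two-sided p-value between ERD and
#' each available branch hydraulic trait: maximum stem conductivity, turgor
#' loss point, stem potential at 88% conductivity loss, and the aboveground
#' safety margin. Deeper ERD is coded as a larger depth value. Traits with
#' fewer than `min_species` complete pairs are skipped.
#'
#' @param erd data.frame `species`, `erd_m`.
#' @param traits data.frame `species` plus any of `kmax_stem`, `psi_tlp`,
#'   `psi88_stem`, `safety_margin`.
#' @param min_species minimum complete species pairs per trait.
#' @return data.frame `trait`, `n`, `rho`, `p`.
#' @export
erd_trait_correlation <- function(erd, traits, min_species = 4) {
  trait_cols <- intersect(c("kmax_stem", "psi_tlp", "psi88_stem", "safety_margin"),
                          names(traits))
  m <- merge(erd[, c("species", "erd_m")], traits, by = "species")
  rows <- list()
  for (tc in trait_cols) {
    ok <- is.finite(m$erd_m) & is.finite(m[[tc]])
    if (sum(ok) < min_species) {
      message("skipping trait ", tc, ": only ", sum(ok), " species")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(m$erd_m[ok], m[[tc]][ok], method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(
      trait = tc, n = sum(ok), rho = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
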