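#' Standardize a series to the unit interval
#'
#' `(x - min) / (max - min)` over the whole series. A constant series is
#' degenerate; by default it raises an error, but the growth-limitation factor
#' maps it to 1 (a constant FLC imposes no differential limitation).
#'
#' @param x numeric vector.
#' @param degenerate `"error"` or `"one"`.
#' @return Vector in [0, 1].
#' @export
standardize01 <- function(x, degenerate = c("error", "one")) {
  degenerate <- match.arg(degenerate)
  r <- range(x)
  if (!all(is.finite(r))) stop("non-finite values in series to standardize")
  if (r[1] == r[2]) {
    if (degenerate == "one") return(rep(1, length(x)))
    stop("constant series cannot be standardized to [0, 1]")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' GPP proxy from VPD via a polynomial response
#'
#' Growth responds to vapor pressure deficit nonlinearly: assimilation rises
#' with VPD up to a threshold, then falls as stomata close. The proxy
#' evaluates a polynomial in VPD (default quadratic `2v - v^2`, interior
#' maximum at 1 kPa), floors it at zero, and standardizes the result to
#' [0, 1] over the full analysis period (VPD^*).
#'
#' @param vpd daily VPD series, kPa.
#' @param coefficients polynomial coefficients, ascending powers
#'   (constant first).
#' @return Daily VPD^* series in [0, 1].
#' @export
gpp_vpd_proxy <- function(vpd, coefficients = c(0, 2, -1)) {
  raw <- outer(vpd, seq_along(coefficients) - 1, `^`) %*% coefficients
  raw <- pmax(as.numeric(raw), 0)
  standardize01(raw)
}

#' Growth model structures
#'
#' The inverse rooting-depth model regresses species growth on interval means
#' of daily growth factors built from the standardized fractional leaf
#' conductance FLC* (standardized within species over the full period) and the
#' standardized GPP-from-VPD proxy VPD^*:
#' \describe{
#'   \item{`main`}{single regressor, interval mean of FLC* x VPD^*.}
#'   \item{`additive`}{two regressors, interval means of FLC* and of VPD^*.}
#'   \item{`multiplicative-lai`}{single regressor, interval mean of
#'     FLC* x VPD^* x LAI*, with a species seasonal leaf-area-index curve.}
#' }
#' @name growth_structures
#' @keywords internal
NULL

growth_structures <- c("main", "additive", "multiplicative-lai")

# interval-mean operator: day-index vector with NA for excluded days
interval_weights <- function(intervals) {
  ok <- !is.na(intervals)
  ids <- sort(unique(intervals[ok]))
  W <- matrix(0, length(intervals), length(ids))
  for (j in seq_along(ids)) {
    d <- which(ok & intervals == ids[j])
    W[d, j] <- 1 / length(d)
  }
  W
}

#' Per-interval growth factors for one species at one depth
#'
#' Computes the daily FLC from the species vulnerability curve and the water
#' potential series at a depth, standardizes it within species over the full
#' period (a constant FLC maps to 1), combines it with VPD^* (and LAI* for the
#' LAI structure), and averages over the days of each census interval.
#'
#' @param curve a [vulnerability_curve()].
#' @param psi_z daily water potential series at the depth, MPa.
#' @param vpd_hat daily VPD^* series from [gpp_vpd_proxy()].
#' @param intervals day-to-interval index (`NA` days excluded), as from
#'   [census_intervals()].
#' @param structure one of `"main"`, `"additive"`, `"multiplicative-lai"`.
#' @param lai daily standardized LAI series (required for the LAI structure).
#' @return For single-factor structures, a vector of interval means; for
#'   `additive`, a matrix with columns `flc` and `vpd`.
#' @export
growth_factor <- function(curve, psi_z, vpd_hat, intervals,
                          structure = "main", lai = NULL) {
  structure <- match.arg(structure, growth_structures)
  if (length(psi_z) != length(vpd_hat) || length(psi_z) != length(intervals))
    stop("psi, VPD^ and interval calendars are misaligned")
  flc_star <- standardize01(flc(psi_z, curve), degenerate = "one")
  W <- interval_weights(intervals)
  switch(structure,
    "main" = as.numeric((flc_star * vpd_hat) %*% W),
    "additive" = cbind(flc = as.numeric(flc_star %*% W),
                       vpd = as.numeric(vpd_hat %*% W)),
    "multiplicative-lai" = {
      if (is.null(lai)) stop("LAI structure requires a daily LAI series")
      as.numeric((flc_star * vpd_hat * lai) %*% W)
    })
}

#' Interval-mean factor array for all species and depths
#'
#' @param psi matrix layer x day of water potential.
#' @param curves named list of [vulnerability_curve()] per species.
#' @param vpd_hat daily VPD^* series.
#' @param intervals day-to-interval index.
#' @param structure growth model structure (single-factor structures only;
#'   the additive structure's FLC component is obtained with
#'   `structure = "additive"` via [growth_factor()]).
#' @param lai optional species x day matrix of standardized LAI.
#' @return Array species x depth x interval of factor means.
#' @export
interval_factor_array <- function(psi, curves, vpd_hat, intervals,
                                  structure = "main", lai = NULL) {
  structure <- match.arg(structure, c("main", "multiplicative-lai"))
  W <- interval_weights(intervals)
  n_sp <- length(curves)
  out <- array(NA_real_, dim = c(n_sp, nrow(psi), ncol(W)),
               dimnames = list(names(curves), NULL, NULL))
  abs_psi <- abs(psi)
  for (i in seq_len(n_sp)) {
    f <- exp(-curves[[i]]$B * abs_psi)            # FLC by depth x day
    f <- t(apply(f, 1, standardize01, degenerate = "one"))
    daily <- sweep(f, 2, vpd_hat, `*`)
    if (structure == "multiplicative-lai")
      daily <- sweep(daily, 2, lai[i, ], `*`)
    out[i, , ] <- daily %*% W
  }
  out
}

#' Fit the inverse growth model at every candidate depth
#'
#' Ordinary least squares of the species growth series on the interval-mean
#' growth factor at each depth of the grid; the best depth maximizes R^2
#' (equivalently minimizes SSE), ties broken to the shallower depth.
#'
#' @param g species growth series, one value per census interval.
#' @param factors depth x interval matrix of factor means (single-factor
#'   structures), or, for the additive structure, a list
#'   `list(flc = depth x interval matrix, vpd = interval vector)`.
#' @param depths candidate depths, m (ascending; rows of `factors`).
#' @return List: `fits` (data.frame `depth`, `beta0`, `beta1`, `r2`,
#'   `resid_sd`), `best_depth` (m), `best_layer` (index), `best_r2`.
#' @export
fit_depth <- function(g, factors, depths) {
  additive <- is.list(factors) && !is.data.frame(factors)
  fmat <- if (additive) factors$flc else factors
  if (!is.matrix(fmat) || nrow(fmat) != length(depths))
    stop("factor matrix must have one row per candidate depth")
  n_int <- length(g)
  if (ncol(fmat) != n_int) stop("growth series and factors disagree on interval count")
  n_par <- if (additive) 3L else 2L
  if (n_int < 3 || n_int <= n_par - 1)
    stop("need at least 3 census intervals (and more intervals than coefficients)")
  n_z <- length(depths)
  beta0 <- beta1 <- r2 <- rsd <- numeric(n_z)
  for (zi in seq_len(n_z)) {
    if (additive) {
      fit <- stats::lm(g ~ fmat[zi, ] + factors$vpd)
      s <- summary(fit)
      beta0[zi] <- stats::coef(fit)[1]
      beta1[zi] <- stats::coef(fit)[2]
      r2[zi] <- s$r.squared
      rsd[zi] <- s$sigma
    } else {
      x <- fmat[zi, ]
      vx <- stats::var(x)
      if (vx == 0) { # constant factor explains nothing
        beta0[zi] <- mean(g); beta1[zi] <- 0; r2[zi] <- 0
        rsd[zi] <- stats::sd(g)
        next
      }
      b1 <- stats::cov(x, g) / vx
      b0 <- mean(g) - b1 * mean(x)
      res <- g - (b0 + b1 * x)
      tss <- sum((g - mean(g))^2)
      beta0[zi] <- b0; beta1[zi] <- b1
      r2[zi] <- if (tss == 0) 0 else 1 - sum(res^2) / tss
      rsd[zi] <- sqrt(sum(res^2) / (n_int - 2))
    }
  }
  best <- which.max(r2)   # first maximum = shallowest on ties
  list(fits = data.frame(depth = depths, beta0 = beta0, beta1 = beta1,
                         r2 = r2, resid_sd = rsd),
       best_depth = depths[best], best_layer = best, best_r2 = r2[best])
}

#' Combine per-realization best depths into an ERD estimate
#'
#' ERD is the median of the best-fit depths across hydrological realizations
#' (the lower median for even counts, so the estimate stays on the depth
#' grid); its SE is the standard deviation of the best depths divided by the
#' square root of the number of realizations.
#'
#' @param best_depths best-fit depth (m) per realization.
#' @return List `erd` (m), `se` (m), `best_depths`.
#' @export
estimate_erd <- function(best_depths) {
  n <- length(best_depths)
  if (n == 0) stop("no realizations supplied")
  s <- sort(best_depths)
  erd <- s[floor((n + 1) / 2)]
  se <- if (n > 1) stats::sd(best_depths) / sqrt(n) else 0
  list(erd = erd, se = se, best_depths = best_depths)
}

#' Estimate effective rooting depths from a hydrological ensemble
#'
#' For every realization and species, regresses the species growth series on
#' the interval-mean growth factor at each grid depth, takes the best-fit
#' depth (max R^2), and summarizes depths across realizations with
#' [estimate_erd()].
#'
#' @param ensemble a `wp_ensemble`.
#' @param growth data.frame `species`, `interval`, `G`.
#' @param curves named list of [vulnerability_curve()] per species.
#' @param vpd_hat daily VPD^* series.
#' @param intervals day-to-interval index ([census_intervals()]).
#' @param structure growth model structure (see [growth_factor()]).
#' @param lai species x day standardized LAI matrix (LAI structure only).
#' @return List: `erd` (data.frame `species`, `erd_m`, `se_m`, `erd_layer`,
#'   `n_realizations`), `best_depths` (species x realization matrix, m).
#' @export
fit_erd <- function(ensemble, growth, curves, vpd_hat, intervals,
                    structure = "main", lai = NULL) {
  stopifnot(inherits(ensemble, "wp_ensemble"))
  structure <- match.arg(structure, growth_structures)
  sp <- names(curves)
  n_r <- dim(ensemble$psi)[1]
  depths <- ensemble$grid$z
  g_list <- lapply(sp, function(s) {
    gi <- growth[growth$species == s, ]
    gi$G[order(gi$interval)]
  })
  names(g_list) <- sp
  best <- matrix(NA_real_, length(sp), n_r, dimnames = list(sp, NULL))
  W <- interval_weights(intervals)
  for (r in seq_len(n_r)) {
    psi_r <- ensemble$psi[r, , ]
    if (structure == "additive") {
      vpd_means <- as.numeric(vpd_hat %*% W)
      for (i in seq_along(sp)) {
        f <- exp(-curves[[i]]$B * abs(psi_r))
        f <- t(apply(f, 1, standardize01, degenerate = "one"))
        fmat <- f %*% W
        best[i, r] <- fit_depth(g_list[[i]],
                                list(flc = fmat, vpd = vpd_means),
                                depths)$best_depth
      }
    } else {
      fac <- interval_factor_array(psi_r, curves, vpd_hat, intervals,
                                   structure = structure, lai = lai)
      for (i in seq_along(sp))
        best[i, r] <- fit_depth(g_list[[i]], fac[i, , ], depths)$best_depth
    }
  }
  est <- lapply(seq_along(sp), function(i) estimate_erd(best[i, ]))
  erd <- data.frame(
    species = sp,
    erd_m = vapply(est, `[[`, numeric(1), "erd"),
    se_m = vapply(est, `[[`, numeric(1), "se"),
    n_realizations = n_r, stringsAsFactors = FALSE)
  erd$erd_layer <- match(erd$erd_m, depths)
  list(erd = erd, best_depths = best)
}

#' Validate rooting-depth estimates against xylem-water isotopes
#'
#' Simple linear regression of estimated ERD on xylem-water delta-2H for the
#' species present in both tables. Given a monotone depth gradient of soil
#' water delta-2H, a good ERD model explains a large fraction of the
#' isotope variance.
#'
#' @param erd data.frame `species`, `erd_m` (from [fit_erd()]).
#' @param isotopes data.frame `species`, `d2h_xylem`.
#' @return List `r2`, `p`, `slope`, `intercept`, `n`.
#' @export
validate_isotopes <- function(erd, isotopes) {
  m <- merge(erd[, c("species", "erd_m")],
             isotopes[, c("species", "d2h_xylem")], by = "species")
  if (nrow(m) < 3) stop("need at least 3 overlapping species, got ", nrow(m))
  fit <- stats::lm(erd_m ~ d2h_xylem, data = m)
  s <- summary(fit)
  p <- if (stats::var(m$d2h_xylem) == 0) NA_real_ else
    s$coefficients["d2h_xylem", "Pr(>|t|)"]
  list(r2 = s$r.squared, p = p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(m))
}

#' Select the growth model structure by isotope validation
#'
#' Runs the full depth inversion under each candidate structure, regresses the
#' resulting ERD estimates against xylem-water isotopes, and ranks structures
#' by validation R^2 (ties keep the candidate order, which lists simpler
#' structures first).
#'
#' @param community a [synth_community()] list, or any list providing
#'   `ensemble`, `growth`, `curves`, `vpd_hat`, `intervals`, `lai`, `isotopes`.
#' @param structures candidate structures, ranked-preference order.
#' @param isotope_species optional subset of species to validate against.
#' @param d2h_max species with xylem delta-2H above this cutoff (per mil) are
#'   excluded from validation: the shallow end of the soil isotope profile is
#'   steeply curved and isotopically ambiguous, so validation uses the deeper,
#'   near-linear portion of the depth-isotope relationship.
#' @return List: `best` (structure name), `ranking` (data.frame `structure`,
#'   `r2`, `p`, `n`), `erd` (named list of ERD tables per structure).
#' @export
select_structure <- function(community, structures = growth_structures,
                             isotope_species = NULL, d2h_max = -40) {
  iso <- community$isotopes
  if (!is.null(isotope_species)) iso <- iso[iso$species %in% isotope_species, ]
  if (!is.null(d2h_max)) iso <- iso[iso$d2h_xylem <= d2h_max, ]
  erds <- list()
  rows <- vector("list", length(structures))
  for (k in seq_along(structures)) {
    st <- structures[k]
    res <- fit_erd(community$ensemble, community$growth, community$curves,
                   community$vpd_hat, community$intervals, structure = st,
                   lai = community$lai)
    v <- validate_isotopes(res$erd, iso)
    erds[[st]] <- res$erd
    rows[[k]] <- data.frame(structure = st, r2 = v$r2, p = v$p, n = v$n,
                            stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$r2), ]  # stable: ties keep candidate order
  list(best = ranking$structure[1], ranking = ranking, erd = erds)
}
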