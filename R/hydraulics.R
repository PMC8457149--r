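#' Leaf hydraulic vulnerability curves
#'
#' A vulnerability curve describes the decline of leaf hydraulic conductance
#' with increasingly negative water potential as the exponential
#' \eqn{K_{leaf}(\Psi) = A e^{-B |\Psi|}}, with conductance scale `A`
#' (mmol m-2 s-1 MPa-1, the maximum conductance at \eqn{\Psi = 0}) and decline
#' rate `B` (MPa-1, stored positive). All water potentials are non-positive
#' MPa; the exponent is evaluated on \eqn{|\Psi|} so conductance falls as the
#' soil or leaf dries.
#'
#' @param A conductance at \eqn{\Psi = 0} (> 0).
#' @param B decline rate (> 0), MPa-1.
#' @param source how the curve was obtained: `"fitted"` from measurement pairs
#'   or `"trait-predicted"` from wood specific gravity and leaf mass per area.
#' @param sigma residual standard deviation of the fit (log scale), if known.
#' @return An object of class `vulnerability_curve`.
#' @export
vulnerability_curve <- function(A, B, source = c("fitted", "trait-predicted"),
                                sigma = NA_real_) {
  source <- match.arg(source)
  if (!is.finite(A) || A <= 0) stop("vulnerability curve requires A > 0")
  if (!is.finite(B) || B <= 0) stop("vulnerability curve requires B > 0")
  structure(list(A = A, B = B, source = source, sigma = sigma),
            class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat(sprintf("Leaf vulnerability curve (%s): K(psi) = %.4g * exp(-%.4g |psi|)\n",
              x$source, x$A, x$B))
  cat(sprintf("  Kmax,leaf = %.4g; psi20 = %.4g MPa\n", x$A, psi_at_loss(0.2, x)))
  invisible(x)
}

#' Fit a leaf vulnerability curve to conductance--water-potential pairs
#'
#' Least-squares fit of \eqn{K = A e^{-B|\Psi|}}. The fit is initialized from
#' the closed-form log-linear regression of \eqn{\ln K} on \eqn{|\Psi|}
#' (exact on noise-free exponential data) and optionally refined by
#' nonlinear least squares on the original scale.
#'
#' @param psi water potentials, MPa, all <= 0; at least two distinct values.
#' @param k conductances, all > 0, same length as `psi`.
#' @param refine if `TRUE` (default), refine by [stats::nls()] on the natural
#'   scale; if the refinement fails to converge the log-linear fit is kept.
#' @return A [vulnerability_curve()] with `source = "fitted"`.
#' @export
fit_vulnerability <- function(psi, k, refine = TRUE) {
  if (length(psi) != length(k)) stop("psi and k must have the same length")
  if (length(psi) < 3) stop("need at least 3 (psi, K) pairs")
  if (any(!is.finite(psi)) || any(!is.finite(k))) stop("non-finite inputs")
  if (any(psi > 0)) stop("water potentials must be <= 0 MPa")
  if (any(k <= 0)) stop("conductances must be > 0")
  x <- abs(psi)
  if (length(unique(x)) < 2) stop("degenerate design: all pairs at one psi")
  co <- stats::coef(stats::lm(log(k) ~ x))
  A <- exp(unname(co[1]))
  B <- -unname(co[2])
  if (B <= 0) stop("fitted decline rate is not positive: K does not decline with drying")
  sigma <- stats::sd(log(k) - (log(A) - B * x))
  if (refine) {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(k ~ A * exp(-B * x), start = list(A = A, B = B),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      if (is.finite(p[["A"]]) && is.finite(p[["B"]]) && p[["A"]] > 0 && p[["B"]] > 0) {
        A <- unname(p[["A"]]); B <- unname(p[["B"]])
      }
    }
  }
  vulnerability_curve(A, B, source = "fitted", sigma = sigma)
}

#' Predict the vulnerability decline rate B from wood and leaf traits
#'
#' Polynomial trait proxy for the decline rate of the leaf vulnerability
#' curve from wood specific gravity (WSG, g cm-3) and leaf mass per unit
#' area (LMA, g m-2):
#' \deqn{B = 5.57 - 20.7\,WSG + 14.99\,WSG^2 - 0.004\,WSG\,LMA
#'       + 0.09\,LMA - 0.0001\,LMA^2}
#'
#' @param wsg wood specific gravity, g cm-3 (> 0).
#' @param lma leaf mass per unit area, g m-2 (> 0).
#' @return Predicted B (MPa-1). Non-positive predictions are returned as-is
#'   with a warning: such species must be flagged and excluded from
#'   trait-predicted curves rather than clamped.
#' @export
predict_B <- function(wsg, lma) {
  if (any(wsg <= 0) || any(lma <= 0)) stop("WSG and LMA must be positive")
  b <- 5.57 - 20.7 * wsg + 14.99 * wsg^2 - 0.004 * wsg * lma +
    0.09 * lma - 0.0001 * lma^2
  if (any(b <= 0))
    warning("non-positive predicted B: trait-predicted curve unusable for ",
            sum(b <= 0), " species")
  b
}

#' Predict the conductance scale A from B and leaf mass per area
#'
#' Polynomial trait proxy for the conductance scale of the leaf vulnerability
#' curve:
#' \deqn{A = -2.36 - 4.42 B - 0.3 B^2 + 0.12 B\,LMA + 0.08\,LMA - 0.001\,LMA^2}
#'
#' @param B decline rate from [predict_B()] or a fitted curve.
#' @param lma leaf mass per unit area, g m-2 (> 0).
#' @return Predicted A. Non-positive predictions are returned as-is with a
#'   warning (species flagged, curve unusable).
#' @export
predict_A <- function(B, lma) {
  if (any(lma <= 0)) stop("LMA must be positive")
  a <- -2.36 - 4.42 * B - 0.3 * B^2 + 0.12 * B * lma + 0.08 * lma - 0.001 * lma^2
  if (any(a <= 0))
    warning("non-positive predicted A: trait-predicted curve unusable for ",
            sum(a <= 0), " species")
  a
}

#' Leaf hydraulic conductance at a given water potential
#'
#' @param psi water potential, MPa, <= 0 (vector allowed).
#' @param curve a [vulnerability_curve()].
#' @return Conductance \eqn{A e^{-B|\Psi|}}, same units as `A`.
#' @export
kleaf <- function(psi, curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(psi > 0)) stop("water potential must be <= 0 MPa")
  curve$A * exp(-curve$B * abs(psi))
}

#' Fractional loss-free leaf conductance (FLC)
#'
#' The ratio of current to maximum leaf conductance,
#' \eqn{FLC(\Psi) = K(\Psi)/K_{max}} = \eqn{e^{-B|\Psi|}}; independent of `A`,
#' in (0, 1], equal to 1 at saturation. Used as the soil-moisture growth
#' limitation factor of the rooting-depth inversion.
#'
#' @inheritParams kleaf
#' @return FLC in (0, 1].
#' @export
flc <- function(psi, curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(psi > 0)) stop("water potential must be <= 0 MPa")
  exp(-curve$B * abs(psi))
}

#' Water potential at a given fractional loss of leaf conductance
#'
#' Inverts the vulnerability curve: the potential at which a fraction `f` of
#' maximum conductance is lost is \eqn{\Psi = \ln(1 - f)/B}. `f = 0.2` gives
#' \eqn{\Psi_{20,leaf}}, used as the species critical threshold
#' \eqn{\Psi_{crit}} in drought-exposure analyses.
#'
#' @param f fractional loss in `[0, 1)`.
#' @param curve a [vulnerability_curve()].
#' @return Water potential, MPa (<= 0).
#' @export
psi_at_loss <- function(f, curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(f < 0) || any(f >= 1)) stop("loss fraction must be in [0, 1)")
  log(1 - f) / curve$B
}
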