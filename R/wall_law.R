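# Elastic--viscoelastic tube law of the 1D vessels and the axial gravity
# source term of the 1D momentum balance.

#' Construct a vessel wall law
#'
#' The transmural pressure of a 1D vessel follows
#' \deqn{p = p_{ext} + p_{ref} + \beta (\sqrt{A} - \sqrt{A_0})/A_0 +
#'       \frac{\gamma}{A_0\sqrt{A}} \frac{\partial A}{\partial t},}
#' an elastic term (coefficient \code{beta}, Pa/m) plus a Kelvin--Voigt
#' viscoelastic correction (coefficient \code{gamma_visc}, Pa s/m).
#'
#' @param beta elastic wall stiffness, Pa/m; must be > 0.
#' @param A0 reference (zero transmural pressure) lumen area, m^2.
#' @param gamma_visc viscoelastic coefficient, Pa s/m; >= 0.
#' @param reference_pressure reference pressure added to the elastic term, Pa.
#' @return An object of class \code{wall_law}.
#' @export
wall_law <- function(beta, A0, gamma_visc = 0, reference_pressure = 0) {
  stopifnot(is.numeric(beta), beta > 0, is.numeric(A0), A0 > 0,
            gamma_visc >= 0)
  structure(list(beta = beta, A0 = A0, gamma_visc = gamma_visc,
                 reference_pressure = reference_pressure),
            class = "wall_law")
}

#' Vessel wall pressure from lumen area
#'
#' Evaluates the elastic--viscoelastic tube law at lumen area \code{A}.
#' Monotone increasing in \code{A} when \code{dA_dt = 0}.
#'
#' @param A lumen area, m^2 (> 0).
#' @param law a \code{\link{wall_law}}.
#' @param dA_dt rate of change of the lumen area, m^2/s.
#' @param p_ext extravascular pressure, Pa.
#' @return Intraluminal pressure, Pa.
#' @export
wall_pressure <- function(A, law, dA_dt = 0, p_ext = 0) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("wall_pressure: non-positive or non-finite lumen area (solver blow-up)",
         call. = FALSE)
  }
  p_ext + law$reference_pressure +
    law$beta * (sqrt(A) - sqrt(law$A0)) / law$A0 +
    law$gamma_visc / (law$A0 * sqrt(A)) * dA_dt
}

#' Pulse wave speed of the elastic tube law
#'
#' \eqn{c(A) = \sqrt{\beta/(2 \rho A_0)}\, A^{1/4}} follows from the
#' characteristic analysis of the 1D system with the elastic tube law.
#'
#' @param A lumen area, m^2. Defaults to the reference area.
#' @param law a \code{\link{wall_law}}.
#' @param rho blood density, kg/m^3.
#' @return Wave speed, m/s.
#' @export
wave_speed <- function(law, A = law$A0, rho = tiltsim_constants$rho_blood) {
  sqrt(law$beta / (2 * rho * law$A0)) * A^0.25
}

#' Axial gravity source term of the 1D momentum balance
#'
#' Body force per unit vessel length exerted by gravity on the blood,
#' measured along the ascending (feet-to-head) direction:
#' \eqn{-\rho g A \sin\alpha \,\ell}, where \eqn{\ell} is the signed
#' projection of the vessel axis onto the head--feet body axis
#' (\eqn{\ell = +1}: vessel runs feetward, \eqn{\ell = -1}: headward).
#' It is therefore negative for feetward-running vessels, where gravity
#' drives flow distally, and vanishes supine (\eqn{\alpha = 0}), where
#' gravity acts perpendicular to the body's long axis.
#'
#' @param ctx list with \code{tilt_angle_alpha} (rad),
#'   \code{longitudinal_projection} (dimensionless in [-1, 1]) and
#'   optionally \code{g} (m/s^2, default 9.81).
#' @param A lumen area, m^2.
#' @param rho blood density, kg/m^3.
#' @return Momentum source, N/m.
#' @export
axial_gravity_term <- function(ctx, A, rho = tiltsim_constants$rho_blood) {
  g <- if (!is.null(ctx$g)) ctx$g else tiltsim_constants$g
  -rho * g * A * sin(ctx$tilt_angle_alpha) * ctx$longitudinal_projection
}
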