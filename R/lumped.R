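# 0D building blocks: Stevino hydrostatic generators, the non-linear
# leg-vein volume law, and the non-ideal-diode venous valve.

#' Hydrostatic pressure gradient across a 0D blood column (Stevino's law)
#'
#' \eqn{\Delta p_h = \rho g h \sin\alpha}, converted to mmHg. The height
#' \code{anatomical_height} is the length of the compartment's blood column
#' projected on the longitudinal body axis; the tilt angle \eqn{\alpha} is
#' the body inclination from horizontal (supine = 0).
#'
#' @param col list with fields \code{rho} (kg/m^3), \code{anatomical_height}
#'   (m, >= 0) and \code{alpha} (rad); \code{g} optional (m/s^2).
#' @return Pressure difference in mmHg.
#' @export
hydrostatic_gradient <- function(col) {
  stopifnot(col$anatomical_height >= 0)
  g <- if (!is.null(col$g)) col$g else tiltsim_constants$g
  Pa_to_mmHg(col$rho * g * col$anatomical_height * sin(col$alpha))
}

#' Non-linear pressure-volume law of the legs venous compartment
#'
#' Distension saturates at high transmural pressure:
#' \deqn{V(p) = V_u + \frac{2\Delta V_{max}}{\pi}
#'   \arctan\!\left(\frac{\pi C_0 p}{2 \Delta V_{max}}\right), \quad p \ge 0,}
#' and is linear with slope \eqn{C_0} for \eqn{p < 0}; the law is
#' continuous and differentiable at zero transmural pressure.
#'
#' @param p_tm transmural pressure, mmHg (vectorized).
#' @param law list with \code{C0} (ml/mmHg, > 0), \code{deltaV_max}
#'   (ml, > 0) and \code{V_u} (ml).
#' @return Volume in ml.
#' @seealso [leg_vein_compliance()], [leg_vein_pressure()]
#' @export
leg_vein_volume <- function(p_tm, law) {
  stopifnot(law$C0 > 0, law$deltaV_max > 0)
  k <- pi * law$C0 / (2 * law$deltaV_max)
  ifelse(p_tm >= 0,
         law$V_u + (2 * law$deltaV_max / pi) * atan(k * p_tm),
         law$V_u + law$C0 * p_tm)
}

#' Local compliance dV/dp of the legs venous law
#'
#' @inheritParams leg_vein_volume
#' @return Compliance in ml/mmHg; equals \code{C0} at zero transmural
#'   pressure and decreases monotonically with distension.
#' @export
leg_vein_compliance <- function(p_tm, law) {
  k <- pi * law$C0 / (2 * law$deltaV_max)
  ifelse(p_tm >= 0, law$C0 / (1 + (k * p_tm)^2), law$C0)
}

#' Inverse of the legs venous pressure-volume law
#'
#' @param V volume, ml (must satisfy V < V_u + deltaV_max).
#' @inheritParams leg_vein_volume
#' @return Transmural pressure in mmHg.
#' @export
leg_vein_pressure <- function(V, law) {
  dv <- V - law$V_u
  if (any(dv >= law$deltaV_max)) {
    stop("leg_vein_pressure: volume beyond asymptotic distension limit",
         call. = FALSE)
  }
  k <- pi * law$C0 / (2 * law$deltaV_max)
  ifelse(dv >= 0, tan(dv * pi / (2 * law$deltaV_max)) / k, dv / law$C0)
}

#' Default parameters for a Mynard-type non-ideal diode valve
#'
#' The valve state \eqn{\zeta \in [0,1]} opens and closes at finite rates
#' driven by the transvalvular pressure difference, and the pressure-flow
#' relation is \eqn{\Delta p = B(\zeta) Q |Q| + L_v(\zeta) \dot Q} with
#' Bernoulli coefficient \eqn{B = \rho/(2 A_{eff}^2)} and effective area
#' \eqn{A_{eff} = A_{min} + \zeta (A_{max} - A_{min})}. A small non-zero
#' \code{A_min} makes the diode leaky (non-ideal), as in venous valves.
#'
#' @param A_max fully open effective area, cm^2.
#' @param A_min leak area when closed, cm^2 (0 allowed for cardiac valves).
#' @param K_open,K_close opening/closing rate coefficients, 1/(mmHg s).
#' @param dp_open,dp_close opening/closing pressure thresholds, mmHg.
#' @param l_eff effective length for the valve inertance, cm.
#' @param R_visc series viscous resistance, mmHg s/ml.
#' @return A list of valve parameters in clinical units.
#' @export
valve_params <- function(A_max, A_min = 0, K_open = 0.3, K_close = 0.3,
                         dp_open = 0, dp_close = 0, l_eff = 1.5,
                         R_visc = 0) {
  stopifnot(A_max > A_min, A_min >= 0, K_open > 0, K_close > 0)
  list(A_max = A_max, A_min = A_min, K_open = K_open, K_close = K_close,
       dp_open = dp_open, dp_close = dp_close, l_eff = l_eff,
       R_visc = R_visc)
}

# Bernoulli coefficient B (mmHg s^2/ml^2) and inertance L (mmHg s^2/ml)
# for an effective valve area in cm^2.
.valve_B <- function(A_eff_cm2, rho = tiltsim_constants$rho_blood) {
  A <- A_eff_cm2 * 1e-4                        # m^2
  (rho / (2 * A^2)) * 1e-12 / tiltsim_constants$mmHg_Pa
}

.valve_L <- function(A_eff_cm2, l_eff_cm, rho = tiltsim_constants$rho_blood) {
  A <- A_eff_cm2 * 1e-4
  (rho * (l_eff_cm * 1e-2) / A) * 1e-6 / tiltsim_constants$mmHg_Pa
}

#' Advance the opening state and flow of a non-ideal diode valve
#'
#' Explicit (Heun) update of
#' \deqn{\dot\zeta = (1-\zeta) K_{open} \max(\Delta p - \Delta p_{open}, 0)
#'   - \zeta K_{close} \max(\Delta p_{close} - \Delta p, 0)}
#' and of the flow momentum equation
#' \eqn{L_v \dot Q = \Delta p - B Q|Q| - R_{visc} Q}.
#'
#' @param vs list with \code{zeta} (in [0,1]) and \code{Q} (ml/s).
#' @param dp pressure difference across the valve, mmHg (held over dt).
#' @param params valve parameters from [valve_params()].
#' @param dt time step, s (> 0).
#' @param rho blood density, kg/m^3.
#' @return Updated list with \code{zeta} and \code{Q}.
#' @export
venous_valve_step <- function(vs, dp, params, dt,
                              rho = tiltsim_constants$rho_blood) {
  stopifnot(dt > 0)
  deriv <- function(zeta, Q) {
    dz <- (1 - zeta) * params$K_open * max(dp - params$dp_open, 0) -
      zeta * params$K_close * max(params$dp_close - dp, 0)
    A_eff <- params$A_min + zeta * (params$A_max - params$A_min)
    A_eff <- max(A_eff, 1e-6)
    B <- .valve_B(A_eff, rho)
    L <- .valve_L(A_eff, params$l_eff, rho)
    dQ <- (dp - B * Q * abs(Q) - params$R_visc * Q) / L
    c(dz, dQ)
  }
  k1 <- deriv(vs$zeta, vs$Q)
  z1 <- min(max(vs$zeta + dt * k1[1], 0), 1)
  q1 <- vs$Q + dt * k1[2]
  k2 <- deriv(z1, q1)
  list(zeta = min(max(vs$zeta + dt * (k1[1] + k2[1]) / 2, 0), 1),
       Q = vs$Q + dt * (k1[2] + k2[2]) / 2)
}

#' Steady orifice flow through a fully defined valve opening
#'
#' Steady-state solution of the valve pressure-flow law: for
#' \code{R_visc = 0} this is the Bernoulli orifice flow
#' \eqn{Q = A_{eff}\sqrt{2\Delta p/\rho}} (converted to ml/s); with a
#' viscous resistance the positive root of
#' \eqn{\Delta p = B Q|Q| + R_{visc} Q} is returned.
#'
#' @param dp pressure difference, mmHg.
#' @param A_eff_cm2 effective open area, cm^2.
#' @param R_visc series viscous resistance, mmHg s/ml.
#' @param rho blood density, kg/m^3.
#' @return Flow in ml/s (signed like \code{dp}).
#' @export
valve_steady_flow <- function(dp, A_eff_cm2, R_visc = 0,
                              rho = tiltsim_constants$rho_blood) {
  B <- .valve_B(A_eff_cm2, rho)
  s <- sign(dp)
  ad <- abs(dp)
  if (R_visc <= 0) return(s * sqrt(ad / B))
  s * (-R_visc + sqrt(R_visc^2 + 4 * B * ad)) / (2 * B)
}

#' Time derivatives of one RLC Windkessel compartment
#'
#' Mass balance on the compliance and momentum balance on the outflow
#' branch, with the Stevino pressure generator in series:
#' \deqn{C \frac{d(p - p_{ext})}{dt} = Q_{in} - Q_{out}, \qquad
#'       L \frac{dQ_{out}}{dt} = p - p_{down} - R Q_{out} + \Delta p_h.}
#' For inertance-free compartments the flow is algebraic,
#' \eqn{Q_{out} = (p - p_{down} + \Delta p_h)/R}.
#'
#' @param state list with \code{p} (mmHg) and \code{Q_out} (ml/s).
#' @param Q_in inflow, ml/s.
#' @param spec list with \code{resistance}, \code{inertance},
#'   \code{compliance} (clinical units).
#' @param p_down downstream pressure, mmHg.
#' @param dp_ext_dt rate of change of the extravascular pressure,
#'   mmHg/s.
#' @param dp_h hydrostatic generator on the outflow link, mmHg.
#' @return List with \code{dp_dt} (mmHg/s) and either \code{dQ_dt}
#'   (ml/s^2) or the algebraic \code{Q_out}.
#' @export
compartment_rates <- function(state, Q_in, spec, p_down, dp_ext_dt = 0,
                              dp_h = 0) {
  stopifnot(spec$compliance > 0, spec$resistance >= 0)
  dp_dt <- (Q_in - state$Q_out) / spec$compliance + dp_ext_dt
  if (spec$inertance > 0) {
    dQ_dt <- (state$p - p_down - spec$resistance * state$Q_out + dp_h) /
      spec$inertance
    list(dp_dt = dp_dt, dQ_dt = dQ_dt)
  } else {
    list(dp_dt = dp_dt,
         Q_out = (state$p - p_down + dp_h) / spec$resistance)
  }
}
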