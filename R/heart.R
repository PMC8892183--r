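# Four-chamber time-varying-elastance heart, cardiac valves and the
# posture-dependent intrathoracic pressure.

#' Time-varying elastance parameters for a heart chamber
#'
#' Chamber transmural pressure is linked to stressed volume through
#' \eqn{p - p_{ext} = E(t) (V - V_u)} with
#' \eqn{E(t) = E_{min} + (E_{max} - E_{min}) e(t)} and a normalized
#' activation \eqn{e(t) \in [0, 1]}. Ventricles use a two-phase
#' (contraction / relaxation) raised-cosine activation whose systolic
#' duration scales with \eqn{\sqrt{RR}}, so systole occupies a growing
#' fraction of the beat as heart rate rises; atria use a single
#' raised-cosine bump placed late in the beat, just before the next
#' ventricular activation.
#'
#' @param E_max,E_min maximum and baseline elastance, mmHg/ml
#'   (\code{E_max >= E_min > 0}).
#' @param V_u unstressed chamber volume, ml.
#' @param chamber_kind \code{"ventricle"} or \code{"atrium"}.
#' @param onset_frac activation onset as a fraction of the RR interval
#'   (ventricles start at the beat boundary).
#' @param k_contract,k_relax contraction and relaxation duration
#'   coefficients: duration in seconds = k * sqrt(RR).
#' @return An object of class \code{elastance_params}.
#' @export
elastance_params <- function(E_max, E_min, V_u,
                             chamber_kind = c("ventricle", "atrium"),
                             onset_frac = 0, k_contract = 0.30,
                             k_relax = 0.15) {
  chamber_kind <- match.arg(chamber_kind)
  stopifnot(E_max >= E_min, E_min > 0, onset_frac >= 0, onset_frac < 1)
  structure(list(E_max = E_max, E_min = E_min, V_u = V_u,
                 chamber_kind = chamber_kind, onset_frac = onset_frac,
                 k_contract = k_contract, k_relax = k_relax),
            class = "elastance_params")
}

#' Normalized elastance activation function
#'
#' @param t_beat time within the beat as a fraction of RR, in [0, 1).
#' @param params an [elastance_params()] object.
#' @param RR beat duration in seconds (sets the systole/diastole balance).
#' @return Dimensionless activation in [0, 1]; 0 at the activation onset,
#'   1 at the time-to-peak.
#' @export
normalized_elastance <- function(t_beat, params, RR = 1) {
  stopifnot(all(t_beat >= 0), all(t_beat < 1), RR > 0)
  tau <- (t_beat - params$onset_frac) %% 1    # beat fraction since onset
  Tc <- params$k_contract * sqrt(RR) / RR     # fractions of the beat
  Tr <- params$k_relax * sqrt(RR) / RR
  if (params$chamber_kind == "ventricle") {
    e <- numeric(length(tau))
    up <- tau < Tc
    dn <- !up & tau < (Tc + Tr)
    e[up] <- 0.5 * (1 - cos(pi * tau[up] / Tc))
    e[dn] <- 0.5 * (1 + cos(pi * (tau[dn] - Tc) / Tr))
    e
  } else {
    Ta <- Tc + Tr                             # single bump, peak at Ta/2
    ifelse(tau < Ta, 0.5 * (1 - cos(2 * pi * tau / Ta)), 0)
  }
}

#' Chamber pressure from the time-varying elastance
#'
#' @param state list with \code{V} (ml).
#' @param E instantaneous elastance, mmHg/ml.
#' @param V_u unstressed volume, ml.
#' @param p_ext extravascular (intrathoracic) pressure, mmHg.
#' @return Pressure in mmHg: \code{E * (V - V_u) + p_ext}.
#' @export
chamber_pressure <- function(state, E, V_u, p_ext = 0) {
  E * (state$V - V_u) + p_ext
}

#' Cardiac valve flow update
#'
#' Same non-ideal diode structure as [venous_valve_step()] with a series
#' viscous resistance; cardiac valves may close completely
#' (\code{A_min = 0}).
#'
#' @param dp pressure difference across the valve, mmHg.
#' @param state list with \code{zeta} and \code{Q} (ml/s).
#' @param params valve parameters from [valve_params()].
#' @param dt time step, s.
#' @param rho blood density, kg/m^3.
#' @return Updated list with \code{zeta} and \code{Q}.
#' @export
cardiac_valve_flow <- function(dp, state, params, dt,
                               rho = tiltsim_constants$rho_blood) {
  venous_valve_step(state, dp, params, dt, rho)
}

#' Intrathoracic pressure as a function of posture
#'
#' Constant at fixed posture, decreasing with body inclination:
#' \eqn{p^{it}(\alpha) = p^{it}_{supine} - \Delta p^{it} \sin\alpha}.
#' Because the tilt angle follows a cosinusoidal ramp in time, the
#' intrathoracic pressure inherits a smooth cosinusoidal transition
#' during tilt. Applied as extravascular pressure to all cardiac
#' chambers and pulmonary compartments.
#'
#' @param alpha tilt angle, rad.
#' @param params list with \code{p_it_supine} (mmHg, negative) and
#'   \code{delta_p_it} (mmHg, >= 0).
#' @return Intrathoracic pressure, mmHg.
#' @export
intrathoracic_pressure <- function(alpha, params) {
  stopifnot(params$p_it_supine < 0, params$delta_p_it >= 0)
  params$p_it_supine - params$delta_p_it * sin(alpha)
}

#' Time derivative of a 2-element pulmonary Windkessel compartment
#'
#' Mass balance on the compliance; the outflow is purely resistive.
#' The extravascular pressure is the intrathoracic pressure, so a step
#' in it shifts the intraluminal pressure one-to-one at constant
#' volume.
#'
#' @param state list with \code{p} (mmHg, intraluminal).
#' @param Q_in inflow, ml/s.
#' @param spec list with \code{resistance} (mmHg s/ml) and
#'   \code{compliance} (ml/mmHg).
#' @param p_down downstream pressure, mmHg.
#' @param dp_ext_dt rate of change of the intrathoracic pressure, mmHg/s.
#' @return List with \code{dp_dt} and the algebraic \code{Q_out}.
#' @export
pulmonary_rates <- function(state, Q_in, spec, p_down, dp_ext_dt = 0) {
  Q_out <- (state$p - p_down) / spec$resistance
  list(dp_dt = (Q_in - Q_out) / spec$compliance + dp_ext_dt, Q_out = Q_out)
}
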