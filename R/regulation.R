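# Short-term control: arterial baroreflex and cardiopulmonary reflex
# sigmoids, first-order effectors, cerebral autoregulation and the
# Davson intracranial-pressure model.

#' Sympathetic and parasympathetic activities from afferent pressure
#'
#' Activities are antagonistic sigmoids of the mean aortic-carotid sinus
#' pressure relative to its (supine) target:
#' \deqn{n_{sym} = \frac{1}{1 + (\bar p / p_t)^{\nu}}, \qquad
#'       n_{para} = \frac{1}{1 + (\bar p / p_t)^{-\nu}},}
#' so that \eqn{n_{sym} + n_{para} = 1}: hypotension
#' (\eqn{\bar p < p_t}) drives sympathetic activation.
#'
#' @param p_mean running mean afferent pressure, mmHg.
#' @param p_target target (supine steady-state) pressure, mmHg (> 0).
#' @param nu sigmoid steepness (dimensionless).
#' @return List with \code{n_sym} and \code{n_para}, both in (0, 1).
#' @export
autonomic_activities <- function(p_mean, p_target, nu = 7) {
  stopifnot(p_target > 0)
  if (any(p_mean <= 0)) {
    warning("autonomic_activities: non-positive afferent pressure clamped")
    p_mean <- pmax(p_mean, 1e-6)
  }
  r <- (p_mean / p_target)^nu
  list(n_sym = 1 / (1 + r), n_para = r / (1 + r))
}

#' First-order effector response to autonomic activity
#'
#' Each effector x follows
#' \eqn{\tau_x \dot x = -x + x_{basal} + G_{sym}(n_{sym} - 1/2)
#'        - G_{para}(n_{para} - 1/2)},
#' clamped to configured bounds, so that the balanced state
#' \eqn{n_{sym} = n_{para} = 1/2} is the basal fixed point (the gains
#' are referenced to the balanced activity; this is the calibration
#' identity of the efferent arm). The parasympathetic gain is non-zero
#' only for heart rate; sympathetic excess raises HR, ventricular
#' contractility and arteriolar resistance and lowers venous unstressed
#' volume and compliance (negative gains on the latter two).
#'
#' @param act list with \code{n_sym}, \code{n_para} (e.g. from
#'   [autonomic_activities()]).
#' @param eff list with \code{value}, \code{basal}, \code{G_sym},
#'   \code{G_para}, \code{tau} (s), \code{lo}, \code{hi}.
#' @param dt time step, s (> 0).
#' @return The effector list with \code{value} advanced by one explicit
#'   Heun step.
#' @export
effector_update <- function(act, eff, dt) {
  stopifnot(dt > 0, eff$tau > 0)
  drive <- eff$basal + eff$G_sym * (act$n_sym - 0.5) -
    eff$G_para * (act$n_para - 0.5)
  f <- function(x) (drive - x) / eff$tau
  k1 <- f(eff$value)
  k2 <- f(eff$value + dt * k1)
  eff$value <- eff$value + dt * (k1 + k2) / 2
  eff$value <- min(max(eff$value, eff$lo), eff$hi)
  eff
}

#' Cardiopulmonary reflex contribution
#'
#' Low-pressure receptors in the right atrium feed the same sigmoid /
#' first-order efferent structure as the arterial baroreflex, with the
#' supine mean right-atrial pressure as target, but act only on
#' peripheral arteriolar resistance and venous tone (unstressed volume
#' and compliance); heart rate and contractility are untouched.
#' Contributions of the two reflexes on shared effectors are additive.
#'
#' @param p_ra_mean running mean right-atrial pressure, mmHg.
#' @param cp_target supine mean right-atrial pressure, mmHg (> 0).
#' @param nu sigmoid steepness.
#' @return List with \code{n_sym}, \code{n_para} of the cardiopulmonary
#'   afferent (to be applied to resistance/venous-tone effectors only).
#' @export
cardiopulmonary_activities <- function(p_ra_mean, cp_target, nu = 7) {
  autonomic_activities(p_ra_mean, cp_target, nu)
}

#' Cerebral autoregulation state update
#'
#' A first-order filter of the relative cerebral-blood-flow error,
#' \eqn{\tau_{aut} \dot x = -x + G_{aut}(\overline{CBF} - CBF_{ref})/CBF_{ref}},
#' drives the cerebral arteriolar compliance through an asymmetric
#' saturating sigmoid (the vasodilation reserve exceeds the
#' vasoconstriction reserve), and arteriolar resistance follows
#' Poiseuille scaling with the arteriolar blood volume,
#' \eqn{R_a = k_R / V_a^2} with \eqn{V_a = C_a p_{tm}}.
#'
#' @param CBF_mean running mean cerebral blood flow, ml/s.
#' @param st list with \code{x_aut}, \code{CBF_ref} (> 0), \code{G_aut},
#'   \code{tau_aut} (s), \code{C_a0}, \code{C_min}, \code{C_max}.
#' @param dt time step, s.
#' @return Updated state with \code{x_aut} and the bounded compliance
#'   \code{C_a}.
#' @export
cerebral_autoregulation <- function(CBF_mean, st, dt) {
  stopifnot(st$CBF_ref > 0, dt > 0)
  err <- st$G_aut * (CBF_mean - st$CBF_ref) / st$CBF_ref
  f <- function(x) (err - x) / st$tau_aut
  k1 <- f(st$x_aut)
  k2 <- f(st$x_aut + dt * k1)
  st$x_aut <- st$x_aut + dt * (k1 + k2) / 2
  st$C_a <- autoreg_compliance(st$x_aut, st$C_a0, st$C_min, st$C_max)
  st
}

#' Asymmetric saturating compliance of the cerebral arterioles
#'
#' Negative filtered error (low flow) dilates toward \code{C_max};
#' positive error constricts toward \code{C_min}; slope at the origin is
#' continuous.
#'
#' @param x filtered relative CBF error (dimensionless).
#' @param C_a0 central (supine) compliance, ml/mmHg.
#' @param C_min,C_max saturation bounds, ml/mmHg.
#' @return Compliance in \code{[C_min, C_max]}.
#' @export
autoreg_compliance <- function(x, C_a0, C_min, C_max) {
  stopifnot(C_min < C_a0, C_a0 < C_max)
  dil <- C_max - C_a0
  con <- C_a0 - C_min
  ifelse(x < 0, C_a0 + dil * tanh(-2 * con * x / dil) ,
         C_a0 - con * tanh(2 * x))
}

#' Poiseuille resistance scaling of the cerebral arterioles
#'
#' @param V_a arteriolar blood volume, ml (> 0).
#' @param k_R Poiseuille constant, mmHg s ml.
#' @return Resistance \code{k_R / V_a^2}, mmHg s/ml.
#' @export
autoreg_resistance <- function(V_a, k_R) {
  stopifnot(all(V_a > 0))
  k_R / V_a^2
}

#' Intracranial pressure (Davson's equation) under posture change
#'
#' \eqn{p^{ic} = R_{csf} I_f + p_{dural}}. Supine, the dural-vein
#' pressure equals the central venous pressure. Tilted with the jugular
#' (superior vena cava) pressure still positive, the dural pressure is
#' the CVP minus the head-to-right-atrium hydrostatic column. Once the
#' jugular pressure reaches zero (angle \eqn{\alpha_{collapse}}), the
#' open fluid column only extends from the head down to the point of
#' collapse at zero transmural pressure; both branches coincide exactly
#' at the collapse condition, so \eqn{p^{ic}} is continuous in
#' \eqn{\alpha}. Applied as extravascular pressure on cerebral veins
#' only.
#'
#' @param cvp central venous (right-atrial) mean pressure, mmHg.
#' @param alpha tilt angle, rad.
#' @param geometry list with \code{h_head_ra} (head-to-right-atrium
#'   distance along the body axis, m) and optionally \code{rho}, \code{g}.
#' @param st list with \code{R_csf} (mmHg s/ml), \code{I_f} (ml/s).
#' @param p_svc superior vena cava (jugular-level) mean pressure, mmHg;
#'   defaults to the hydrostatic continuation of \code{cvp}.
#' @return Intracranial pressure, mmHg.
#' @export
intracranial_pressure <- function(cvp, alpha, geometry, st,
                                  p_svc = NULL) {
  rho <- if (!is.null(geometry$rho)) geometry$rho else tiltsim_constants$rho_blood
  g <- if (!is.null(geometry$g)) geometry$g else tiltsim_constants$g
  grad <- Pa_to_mmHg(rho * g * sin(alpha))          # mmHg per metre
  col_full <- grad * geometry$h_head_ra
  if (is.null(p_svc)) p_svc <- cvp - 0.5 * col_full # mid-column estimate
  if (sin(alpha) <= 0 || p_svc > 0) {
    p_dural <- cvp - col_full
  } else {
    # distance from RA up to the zero-pressure (collapse) point
    d0 <- min(max(cvp, 0) / grad, geometry$h_head_ra)
    p_dural <- -grad * (geometry$h_head_ra - d0)
  }
  st$R_csf * st$I_f + p_dural
}
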