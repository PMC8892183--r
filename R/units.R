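# Unit conversions between internal SI quantities and the clinical units
# (mmHg, ml, s) used in configuration files and outputs.

#' Physical constants used throughout the model
#'
#' @format A list with elements:
#' \describe{
#'   \item{mmHg_Pa}{Pascal per mmHg (133.322).}
#'   \item{g}{Gravitational acceleration, m/s^2.}
#'   \item{rho_blood}{Default blood density, kg/m^3.}
#'   \item{mu_blood}{Default dynamic blood viscosity, Pa s.}
#' }
#' @export
tiltsim_constants <- list(
  mmHg_Pa   = 133.322,
  g         = 9.81,
  rho_blood = 1050,
  mu_blood  = 0.004
)

#' Convert pressure between mmHg and Pa
#'
#' @param x numeric vector of pressures.
#' @return Converted pressures.
#' @export
mmHg_to_Pa <- function(x) x * tiltsim_constants$mmHg_Pa

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / tiltsim_constants$mmHg_Pa

# Hydraulic resistance: 1 mmHg s/ml = 133.322 Pa s / 1e-6 m^3
.R_clin_to_SI <- function(x) x * tiltsim_constants$mmHg_Pa / 1e-6
.R_SI_to_clin <- function(x) x * 1e-6 / tiltsim_constants$mmHg_Pa

deg_to_rad <- function(x) x * pi / 180
rad_to_deg <- function(x) x * 180 / pi
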