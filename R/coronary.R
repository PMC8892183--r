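# Three-layer intramyocardial microcirculation compressed by cavity
# pressure (subepicardium / midwall / subendocardium).

#' Intramyocardial pressure of a myocardial layer
#'
#' The extravascular pressure squeezing the intramyocardial
#' microcirculation is a fixed fraction of the ventricular cavity
#' pressure, increasing from the subepicardium to the subendocardium:
#' default weights 1/6, 1/2 and 5/6. Left-ventricular districts use the
#' LV cavity pressure, right-ventricular districts the RV pressure.
#'
#' @param p_cavity ventricular cavity pressure, mmHg.
#' @param layer one of \code{"subepicardium"}, \code{"midwall"},
#'   \code{"subendocardium"}.
#' @param weights named numeric vector of layer weights.
#' @return Intramyocardial pressure, mmHg.
#' @export
intramyocardial_pressure <- function(p_cavity,
                                     layer = c("subepicardium", "midwall",
                                               "subendocardium"),
                                     weights = c(subepicardium = 1 / 6,
                                                 midwall = 1 / 2,
                                                 subendocardium = 5 / 6)) {
  layer <- match.arg(layer)
  unname(weights[layer]) * p_cavity
}

#' Default parameters of one coronary microcirculatory district
#'
#' Each district drains one main (left or right) coronary artery into
#' three parallel myocardial layers, each an arterial - intermediate -
#' venous RC chain with input/output impedances \code{Z_a}, \code{Z_v},
#' compliances \code{C_a}, \code{C_c}, \code{C_v} and intra-layer
#' resistances \code{R_c1}, \code{R_c2}. Units: mmHg s/ml and ml/mmHg.
#'
#' @param R_total total district resistance at zero intramyocardial
#'   pressure, mmHg s/ml (split equally across the three layers).
#' @param side \code{"left"} or \code{"right"}: which ventricular cavity
#'   pressure compresses the district.
#' @return A list with per-layer parameter vectors and the layer
#'   weights of [intramyocardial_pressure()].
#' @export
coronary_district <- function(R_total = 42, side = c("left", "right")) {
  side <- match.arg(side)
  R_layer <- R_total * 3                       # three parallel layers
  list(side = side,
       layers = c("subepicardium", "midwall", "subendocardium"),
       w_im = c(1 / 6, 1 / 2, 5 / 6),
       Z_a = 0.12 * R_layer, R_c1 = 0.28 * R_layer,
       R_c2 = 0.45 * R_layer, Z_v = 0.15 * R_layer,
       C_a = 0.006, C_c = 0.15, C_v = 0.25)
}
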