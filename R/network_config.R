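# Loading, validating and serializing the closed-loop network model.

.kinds <- c("arteriole", "capillary", "venule", "vein",
            "vena_cava_superior", "vena_cava_inferior",
            "vena_cava_abdominal", "pulmonary_artery", "pulmonary_vein")
.regions <- c("head", "arms", "upper_abdomen", "lower_abdomen", "legs",
              "thorax", "coronary")
.micro_kinds <- c("arteriole", "capillary", "venule")

.cfg_err <- function(...) stop(sprintf(...), call. = FALSE)

#' Load and validate a closed-loop network model
#'
#' Reads a model configuration (YAML or JSON; the dialect is detected
#' from the file extension or content), normalizes units, derives wall
#' stiffness from reference wave speeds where needed, resolves the
#' arterial tree topology, and checks all structural invariants:
#' positive geometry, a rooted arterial tree (single root, no cycles),
#' exactly one terminal bed per leaf vessel, microvascular compartments
#' with zero anatomical height, one capillary / venule / vein per body
#' region, and a complete closed loop. A versioned \code{model_version}
#' field is required.
#'
#' @param config path to a YAML/JSON document, or a raw configuration
#'   list as produced by [serialize_network()]/yaml parsing.
#' @return An object of class \code{network_model}.
#' @export
load_network <- function(config) {
  raw <- if (is.character(config)) {
    if (!file.exists(config)) .cfg_err("configuration file not found: %s", config)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) config else {
    .cfg_err("load_network: config must be a file path or a list")
  }
  if (is.null(raw$model_version)) {
    .cfg_err("configuration error: missing required field 'model_version'")
  }

  vessels <- .build_vessel_table(raw)
  comps <- .build_compartment_table(raw)
  .validate_topology(vessels, comps)
  .validate_compartments(comps)

  blood <- raw$blood
  if (is.null(blood$total_volume) || blood$total_volume <= 0) {
    .cfg_err("validation error: blood.total_volume must be > 0")
  }

  model <- structure(list(
    model_version = raw$model_version,
    name = if (!is.null(raw$name)) raw$name else "unnamed",
    blood = blood,
    vessels = vessels,
    compartments = comps,
    chambers = raw$chambers,
    cardiac_valves = raw$cardiac_valves,
    venous_valves = raw$venous_valves,
    heart_rate = if (!is.null(raw$heart_rate)) raw$heart_rate else 68,
    intrathoracic = raw$intrathoracic,
    coronary = raw$coronary,
    regulation = raw$regulation,
    sites = raw$sites,
    root_z = if (!is.null(raw$root_z)) raw$root_z else 0,
    reference_pressure_mmHg =
      if (!is.null(raw$reference_pressure_mmHg)) raw$reference_pressure_mmHg else 80,
    raw = raw
  ), class = "network_model")
  model
}

# Vessel list -> data.frame with derived beta, z coordinates, children.
.build_vessel_table <- function(raw) {
  vs <- raw$vessels
  if (is.null(vs) || !length(vs)) .cfg_err("configuration error: no vessels")
  rho <- raw$blood$density
  ids <- vapply(vs, function(v) as.integer(v$id), integer(1))
  if (anyDuplicated(ids)) {
    .cfg_err("configuration error: duplicate vessel id %d",
             ids[duplicated(ids)][1])
  }
  df <- data.frame(
    id = ids,
    name = vapply(vs, function(v) as.character(v$name), character(1)),
    length = vapply(vs, function(v) as.numeric(v$length), numeric(1)),
    proximal_radius = vapply(vs, function(v) as.numeric(v$proximal_radius), numeric(1)),
    distal_radius = vapply(vs, function(v) as.numeric(v$distal_radius), numeric(1)),
    parent_id = vapply(vs, function(v)
      if (is.null(v$parent)) NA_integer_ else as.integer(v$parent), integer(1)),
    longitudinal_projection = vapply(vs, function(v)
      as.numeric(v$longitudinal_projection), numeric(1)),
    orientation_gamma = vapply(vs, function(v)
      deg_to_rad(if (!is.null(v$orientation_gamma_deg))
        v$orientation_gamma_deg else rad_to_deg(asin(abs(v$longitudinal_projection)))),
      numeric(1)),
    gamma_visc = vapply(vs, function(v)
      if (is.null(v$gamma_visc)) 0 else as.numeric(v$gamma_visc), numeric(1)),
    terminal_bed_id = vapply(vs, function(v)
      if (is.null(v$terminal_bed) || identical(v$terminal_bed, "~"))
        NA_character_ else as.character(v$terminal_bed), character(1)),
    stringsAsFactors = FALSE
  )
  # wall stiffness: explicit beta or derived from reference wave speed
  beta <- vapply(seq_along(vs), function(i) {
    v <- vs[[i]]
    if (!is.null(v$wall_stiffness_beta)) return(as.numeric(v$wall_stiffness_beta))
    if (is.null(v$wave_speed_ref)) {
      .cfg_err("vessel %d: needs wall_stiffness_beta or wave_speed_ref", df$id[i])
    }
    r0 <- (df$proximal_radius[i] + df$distal_radius[i]) / 2
    A0 <- pi * r0^2
    2 * rho * v$wave_speed_ref^2 * sqrt(A0)
  }, numeric(1))
  df$wall_stiffness_beta <- beta

  if (any(df$length <= 0)) {
    .cfg_err("validation error: vessel %d: length must be > 0",
             df$id[which(df$length <= 0)[1]])
  }
  if (any(df$proximal_radius <= 0) || any(df$distal_radius <= 0)) {
    .cfg_err("validation error: vessel radii must be > 0")
  }
  if (any(abs(df$longitudinal_projection) > 1)) {
    .cfg_err("validation error: vessel %d: |longitudinal_projection| must be <= 1",
             df$id[which(abs(df$longitudinal_projection) > 1)[1]])
  }
  df
}

.build_compartment_table <- function(raw) {
  cs <- raw$compartments
  if (is.null(cs) || !length(cs)) .cfg_err("configuration error: no compartments")
  ids <- vapply(cs, function(x) as.character(x$id), character(1))
  if (anyDuplicated(ids)) {
    .cfg_err("configuration error: duplicate compartment id '%s'",
             ids[duplicated(ids)][1])
  }
  num_or <- function(x, d = 0) if (is.null(x)) d else as.numeric(x)
  chr_or <- function(x, d = NA_character_) if (is.null(x)) d else as.character(x)
  df <- data.frame(
    id = ids,
    kind = vapply(cs, function(x) chr_or(x$kind), character(1)),
    region = vapply(cs, function(x) chr_or(x$region), character(1)),
    downstream = vapply(cs, function(x) chr_or(x$downstream), character(1)),
    resistance = vapply(cs, function(x) num_or(x$R), numeric(1)),
    inertance = vapply(cs, function(x) num_or(x$L), numeric(1)),
    compliance = vapply(cs, function(x) num_or(x$C), numeric(1)),
    z_midpoint = vapply(cs, function(x) num_or(x$z), numeric(1)),
    anatomical_height = vapply(cs, function(x) num_or(x$height), numeric(1)),
    volume = vapply(cs, function(x) num_or(x$volume), numeric(1)),
    p_init = vapply(cs, function(x) num_or(x$p_init, 10), numeric(1)),
    extravascular = vapply(cs, function(x)
      chr_or(x$extravascular, "ambient"), character(1)),
    valve = vapply(cs, function(x) chr_or(x$valve), character(1)),
    stringsAsFactors = FALSE
  )
  nl <- lapply(cs, function(x) x$nonlinear)
  df$nonlinear_C0 <- vapply(nl, function(x) if (is.null(x)) NA_real_ else x$C0, numeric(1))
  df$nonlinear_dVmax <- vapply(nl, function(x) if (is.null(x)) NA_real_ else x$deltaV_max, numeric(1))
  df
}

.validate_topology <- function(vessels, comps) {
  ids <- vessels$id
  roots <- which(is.na(vessels$parent_id))
  if (length(roots) != 1) {
    .cfg_err("validation error: arterial tree must have exactly one root, found %d",
             length(roots))
  }
  bad <- setdiff(stats::na.omit(vessels$parent_id), ids)
  if (length(bad)) .cfg_err("configuration error: unresolved parent_id %d", bad[1])
  # cycle check by walking to the root from each vessel
  idx <- match(vessels$parent_id, ids)
  for (i in seq_along(ids)) {
    seen <- logical(length(ids))
    j <- i
    while (!is.na(idx[j])) {
      if (seen[j]) {
        .cfg_err("validation error: vessel %d: parent chain forms a cycle (rooted-tree invariant)",
                 ids[i])
      }
      seen[j] <- TRUE
      j <- idx[j]
    }
  }
  has_children <- ids %in% vessels$parent_id
  leaves <- !has_children
  no_bed <- leaves & is.na(vessels$terminal_bed_id)
  if (any(no_bed)) {
    .cfg_err("validation error: leaf vessel %d has no terminal_bed_id",
             vessels$id[which(no_bed)[1]])
  }
  term <- stats::na.omit(vessels$terminal_bed_id)
  known <- c(comps$id, "coronary_left", "coronary_right")
  bad <- setdiff(term, known)
  if (length(bad)) .cfg_err("configuration error: unresolved terminal bed '%s'", bad[1])
}

.validate_compartments <- function(comps) {
  bad <- setdiff(comps$kind, .kinds)
  if (length(bad)) .cfg_err("validation error: unknown compartment kind '%s'", bad[1])
  bad <- setdiff(comps$region, .regions)
  if (length(bad)) .cfg_err("validation error: unknown region '%s'", bad[1])
  if (any(comps$resistance < 0)) .cfg_err("validation error: resistance must be >= 0")
  if (any(comps$compliance <= 0)) {
    .cfg_err("validation error: compartment '%s': compliance must be > 0",
             comps$id[which(comps$compliance <= 0)[1]])
  }
  if (any(comps$inertance < 0)) .cfg_err("validation error: inertance must be >= 0")
  if (any(comps$volume < 0)) .cfg_err("validation error: volumes must be >= 0")
  micro <- comps$kind %in% .micro_kinds
  if (any(micro & comps$anatomical_height != 0)) {
    .cfg_err(paste0("validation error: compartment '%s': anatomical_height must be 0 ",
                    "for microvascular kinds (confined districts carry no hydrostatic column)"),
             comps$id[which(micro & comps$anatomical_height != 0)[1]])
  }
  # one capillary, one venule, one vein per perfused region
  for (r in intersect(unique(comps$region),
                      c("head", "arms", "upper_abdomen", "lower_abdomen", "legs"))) {
    for (k in c("capillary", "venule", "vein")) {
      n <- sum(comps$region == r & comps$kind == k)
      if (n != 1) {
        .cfg_err("validation error: region '%s' must have exactly one %s, found %d",
                 r, k, n)
      }
    }
  }
  # closed loop: every compartment drains somewhere known
  targets <- c(comps$id, "ra", "la")
  bad <- setdiff(comps$downstream, targets)
  if (length(bad)) {
    .cfg_err("validation error: compartment downstream '%s' does not resolve (closed loop incomplete)",
             bad[1])
  }
  invisible(TRUE)
}

#' Serialize a network model back to a configuration document
#'
#' Writes the raw configuration (JSON dialect) so that
#' \code{load_network(serialize_network(model, path))} reproduces all
#' fields exactly.
#'
#' @param model a \code{network_model}.
#' @param path output file path (".json").
#' @return \code{path}, invisibly.
#' @export
serialize_network <- function(model, path) {
  jsonlite::write_json(model$raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, always_decimal = TRUE)
  invisible(path)
}

#' Distribute total blood volume over compartments
#'
#' Allocates \code{total} according to \code{fractions} (which must sum
#' to one within 1e-9). The allocation is exact: any floating-point
#' remainder is corrected on the compartment with the largest
#' allocation, so the outputs sum to \code{total} to machine precision.
#'
#' @param total total blood volume, ml (> 0).
#' @param fractions named numeric vector of dimensionless fractions.
#' @return Named numeric vector of volumes in ml summing to \code{total}.
#' @export
distribute_blood_volume <- function(total, fractions) {
  stopifnot(total > 0, length(fractions) > 0)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) {
    .cfg_err("distribute_blood_volume: fractions sum to %.12f, not 1", s)
  }
  out <- total * fractions / s
  k <- which.max(out)
  out[k] <- out[k] + (total - sum(out))
  out
}

#' Small fully parameterized fixture networks for solver verification
#'
#' \describe{
#'   \item{single_vessel}{one uniform 1D vessel (no taper, 1 m, aortic
#'     caliber) with configurable end conditions; no 0D compartments.}
#'   \item{symmetric_bifurcation}{a parent vessel splitting into two
#'     identical children.}
#'   \item{minimal_closed_loop}{a four-chamber heart, one artery and a
#'     single arteriole-capillary-venule-vein-cava RLC chain closing the
#'     loop through the pulmonary circulation.}
#' }
#'
#' @return Named list with elements \code{single_vessel},
#'   \code{symmetric_bifurcation} (plain parameter lists consumed by the
#'   1D test drivers) and \code{minimal_closed_loop} (a validated
#'   \code{network_model}).
#' @export
fixture_networks <- function() {
  uni <- list(length = 1.0, radius = 0.010, wave_speed_ref = 5.0,
              gamma_visc = 0, rho = 1050, n_vessels = 1, n_compartments = 0)
  bif <- list(
    parent = list(length = 0.3, radius = 0.010, wave_speed_ref = 5.0),
    child = list(length = 0.3, radius = 0.0072, wave_speed_ref = 5.5),
    rho = 1050, n_children = 2
  )
  loop_cfg <- .minimal_loop_config()
  list(single_vessel = uni, symmetric_bifurcation = bif,
       minimal_closed_loop = load_network(loop_cfg))
}

.minimal_loop_config <- function() {
  list(
    model_version = 1,
    name = "minimal_closed_loop",
    blood = list(density = 1050, viscosity = 0.004, total_volume = 5700,
                 zeta_profile = 9, chi_profile = 1.1),
    root_z = 0,
    reference_pressure_mmHg = 80,
    vessels = list(list(
      id = 1, name = "aorta", parent = NULL, length = 0.4,
      proximal_radius = 0.012, distal_radius = 0.010, wave_speed_ref = 5.0,
      gamma_visc = 0, longitudinal_projection = 0, orientation_gamma_deg = 0,
      terminal_bed = "sys_arteriole")),
    sites = list(aortic_root = list(vessel = 1, position = 0)),
    compartments = list(
      list(id = "sys_arteriole", kind = "arteriole", region = "upper_abdomen",
           downstream = "sys_capillary", R = 0.9, L = 0.003, C = 0.6,
           z = 0, height = 0, volume = 120, p_init = 70,
           extravascular = "ambient"),
      list(id = "sys_capillary", kind = "capillary", region = "upper_abdomen",
           downstream = "sys_venule", R = 0.12, L = 0.001, C = 1.5,
           z = 0, height = 0, volume = 260, p_init = 26,
           extravascular = "ambient"),
      list(id = "sys_venule", kind = "venule", region = "upper_abdomen",
           downstream = "sys_vein", R = 0.08, L = 0.001, C = 10,
           z = 0, height = 0, volume = 500, p_init = 19,
           extravascular = "ambient"),
      list(id = "sys_vein", kind = "vein", region = "upper_abdomen",
           downstream = "cava", R = 0.05, L = 0.0005, C = 70,
           z = 0, height = 0, volume = 3000, p_init = 11,
           extravascular = "ambient"),
      list(id = "cava", kind = "vena_cava_inferior", region = "thorax",
           downstream = "ra", R = 0.01, L = 0.0003, C = 15,
           z = 0, height = 0, volume = 600, p_init = 8,
           extravascular = "intrathoracic"),
      list(id = "pulmonary_artery", kind = "pulmonary_artery", region = "thorax",
           downstream = "pulmonary_vein", R = 0.035, L = 0, C = 4,
           z = 0, height = 0, volume = 160, p_init = 16,
           extravascular = "intrathoracic"),
      list(id = "pulmonary_vein", kind = "pulmonary_vein", region = "thorax",
           downstream = "la", R = 0.025, L = 0, C = 12,
           z = 0, height = 0, volume = 400, p_init = 10,
           extravascular = "intrathoracic")),
    chambers = list(
      ra = list(E_max = 0.30, E_min = 0.17, V_u = 14, kind = "atrium",
                onset_frac = 0.80, k_contract = 0.09, k_relax = 0.09,
                volume = 64, z = 0),
      rv = list(E_max = 0.65, E_min = 0.045, V_u = 18, kind = "ventricle",
                onset_frac = 0, k_contract = 0.30, k_relax = 0.15,
                volume = 120, z = 0),
      la = list(E_max = 0.32, E_min = 0.18, V_u = 12, kind = "atrium",
                onset_frac = 0.80, k_contract = 0.09, k_relax = 0.09,
                volume = 68, z = 0),
      lv = list(E_max = 2.6, E_min = 0.10, V_u = 15, kind = "ventricle",
                onset_frac = 0, k_contract = 0.30, k_relax = 0.15,
                volume = 130, z = 0)),
    cardiac_valves = list(
      tricuspid = list(A_max = 6.0, A_min = 0, K_open = 30, K_close = 40,
                       l_eff = 1.2, R_visc = 0.003),
      pulmonary = list(A_max = 4.2, A_min = 0, K_open = 30, K_close = 40,
                       l_eff = 1.0, R_visc = 0.005),
      mitral = list(A_max = 5.0, A_min = 0, K_open = 30, K_close = 40,
                    l_eff = 1.2, R_visc = 0.004),
      aortic = list(A_max = 4.0, A_min = 0, K_open = 30, K_close = 40,
                    l_eff = 1.0, R_visc = 0.008)),
    venous_valves = list(),
    heart_rate = 68,
    intrathoracic = list(p_it_supine = -4, delta_p_it = 3),
    coronary = list(enabled = FALSE),
    regulation = list(enabled = FALSE)
  )
}

#' Default "healthy male" model configuration path
#'
#' @return Path to the YAML configuration shipped with the package.
#' @export
default_config <- function() {
  system.file("extdata", "healthy_male.yaml", package = "tiltsim",
              mustWork = TRUE)
}
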