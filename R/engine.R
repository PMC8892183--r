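# Coupling the 1D tree and the 0D circulation: protocol runner and
# solver-verification drivers.

#' Numerical controls for the coupled solver
#'
#' @param dt global time step, s (constant; the engine checks the CFL
#'   bound of every vessel and stops with the required dt on violation).
#' @param dx target 1D element size, m (every vessel keeps at least two
#'   elements). The default 0.05 m is the "reduced" desk-scale grid;
#'   0.025 m reproduces the full-resolution setting.
#' @param out_dt output sampling interval, s.
#' @param pre_min_beats,pre_max_beats beat budget for the pre-tilt
#'   steady state.
#' @param post_min_beats,post_max_beats beat budget for each post-ramp
#'   steady state.
#' @param steady_tol relative beat-to-beat tolerance on beat-averaged
#'   MAP and RR defining "steady".
#' @param steady_beats number of consecutive beats that must satisfy
#'   \code{steady_tol}.
#' @param ascent_rate deg/s used for the preparatory tilt-up of a
#'   tilt-down protocol.
#' @param cfl_every steps between CFL audits.
#' @return A list of numerics settings.
#' @export
sim_control <- function(dt = 2e-4, dx = 0.05, out_dt = 0.005,
                        pre_min_beats = 25, pre_max_beats = 120,
                        post_min_beats = 40, post_max_beats = 260,
                        steady_tol = 1e-3, steady_beats = 10,
                        ascent_rate = 4, cfl_every = 25L) {
  list(dt = dt, dx = dx, out_dt = out_dt,
       pre_min_beats = as.integer(pre_min_beats),
       pre_max_beats = as.integer(pre_max_beats),
       post_min_beats = as.integer(post_min_beats),
       post_max_beats = as.integer(post_max_beats),
       steady_tol = steady_tol, steady_beats = as.integer(steady_beats),
       ascent_rate = ascent_rate, cfl_every = as.integer(cfl_every))
}

.kind_code <- function(kind) match(kind, .kinds) - 1L

# assemble the flat C++ model description
.prepare_model <- function(model, numerics, regulation_on = TRUE,
                           coronary_on = NULL) {
  vs <- model$vessels
  comps <- model$compartments
  rho <- model$blood$density
  pref_pa <- mmHg_to_Pa(model$reference_pressure_mmHg)

  coro_requested <- isTRUE(model$coronary$enabled)
  if (!is.null(coronary_on)) coro_requested <- isTRUE(coronary_on)
  if (!coro_requested) {
    # coronary feature off: the coronary ostia leave the tree entirely
    vs <- vs[is.na(vs$terminal_bed_id) |
               !grepl("^coronary_", vs$terminal_bed_id), , drop = FALSE]
  }

  nv <- nrow(vs)
  vidx <- function(id) match(id, vs$id) - 1L
  cidx <- function(id) match(id, comps$id) - 1L

  # z of each vessel's proximal end, walked down from the root
  zp <- rep(NA_real_, nv)
  root <- which(is.na(vs$parent_id))
  zp[root] <- model$root_z
  repeat {
    todo <- which(is.na(zp))
    if (!length(todo)) break
    for (i in todo) {
      pidx <- match(vs$parent_id[i], vs$id)
      if (!is.na(zp[pidx])) {
        zp[i] <- zp[pidx] + vs$longitudinal_projection[pidx] * vs$length[pidx]
      }
    }
  }

  coro_enabled <- coro_requested

  term_comp <- integer(nv)
  for (i in seq_len(nv)) {
    tb <- vs$terminal_bed_id[i]
    term_comp[i] <- if (is.na(tb)) -1L
    else if (tb == "coronary_left") -2L
    else if (tb == "coronary_right") -3L
    else cidx(tb)
  }

  vlist <- lapply(seq_len(nv), function(i) {
    list(name = vs$name[i], length = vs$length[i],
         r_prox = vs$proximal_radius[i], r_dist = vs$distal_radius[i],
         beta = vs$wall_stiffness_beta[i], gamma_visc = vs$gamma_visc[i],
         proj = vs$longitudinal_projection[i],
         term_comp = term_comp[i], z_prox = zp[i])
  })

  junctions <- list()
  for (i in seq_len(nv)) {
    ch <- which(!is.na(vs$parent_id) & vs$parent_id == vs$id[i])
    if (length(ch)) {
      junctions[[length(junctions) + 1]] <-
        list(parent = i - 1L, children = as.integer(ch - 1L))
    }
  }

  # terminal characteristic impedances (SI), at the distal reference area
  term_Z <- vapply(seq_len(nv), function(i) {
    A0 <- pi * vs$distal_radius[i]^2
    c0 <- sqrt(vs$wall_stiffness_beta[i] / (2 * rho * A0)) * A0^0.25
    rho * c0 / A0
  }, numeric(1))

  # venous valve registry (order defines indices)
  vv_names <- names(model$venous_valves)
  vvalve <- rep(-1L, nrow(comps))
  if (length(vv_names)) {
    for (k in seq_along(vv_names)) {
      host <- which(!is.na(comps$valve) & comps$valve == vv_names[k])
      vvalve[host] <- k - 1L
    }
  }
  vv_list <- unname(lapply(model$venous_valves, function(v) {
    list(A_max = v$A_max, A_min = v$A_min, K_open = v$K_open,
         K_close = v$K_close, l_eff = v$l_eff, R_visc = v$R_visc)
  }))

  down <- integer(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    d <- comps$downstream[i]
    down[i] <- if (d == "ra") -1L else if (d == "la") -2L else cidx(d)
  }
  pextsrc <- match(comps$extravascular,
                   c("ambient", "intrathoracic", "intracranial")) - 1L
  kindc <- .kind_code(comps$kind)
  clist <- lapply(seq_len(nrow(comps)), function(i) {
    list(id = comps$id[i], R = comps$resistance[i], L = comps$inertance[i],
         C = comps$compliance[i], z = comps$z_midpoint[i],
         height = comps$anatomical_height[i], down = down[i],
         pextsrc = pextsrc[i], kind = kindc[i], vvalve = vvalve[i],
         is_headart = comps$kind[i] == "arteriole" && comps$region[i] == "head",
         r_ctrl = comps$kind[i] %in% c("arteriole", "capillary") &&
           comps$region[i] != "head",
         vu_ctrl = comps$kind[i] == "vein",
         c_ctrl = comps$kind[i] == "vein",
         nonlinear = !is.na(comps$nonlinear_C0[i]),
         nlC0 = ifelse(is.na(comps$nonlinear_C0[i]), 0, comps$nonlinear_C0[i]),
         nlDV = ifelse(is.na(comps$nonlinear_dVmax[i]), 1,
                       comps$nonlinear_dVmax[i]))
  })

  # coronary districts
  coro <- list()
  if (coro_enabled) {
    for (side in c("left", "right")) {
      d <- coronary_district(R_total = model$coronary[[side]]$R_total,
                             side = side)
      tv <- which(term_comp == ifelse(side == "left", -2L, -3L))
      p0 <- c(70, 30, 12)       # arterial / intermediate / venous init, mmHg
      coro[[length(coro) + 1]] <- list(
        Z_a = rep(d$Z_a, 3), R_c1 = rep(d$R_c1, 3), R_c2 = rep(d$R_c2, 3),
        Z_v = rep(d$Z_v, 3), C_a = rep(d$C_a, 3), C_c = rep(d$C_c, 3),
        C_v = rep(d$C_v, 3), w = d$w_im,
        term_vessel = tv - 1L,
        V_init = as.numeric(vapply(1:3, function(l)
          c(d$C_a * p0[1], d$C_c * p0[2], d$C_v * p0[3]), numeric(3))))
    }
  }

  p1d <- model$reference_pressure_mmHg
  # 1D grid volume at the initial (reference) pressure: cell averages at
  # the cell centers, matching the compiled solver's measure exactly
  v1d <- sum(vapply(seq_len(nv), function(i) {
    ncell <- max(2, ceiling(vs$length[i] / numerics$dx))
    x <- (seq_len(ncell) - 0.5) / ncell
    r <- vs$proximal_radius[i] + (vs$distal_radius[i] - vs$proximal_radius[i]) * x
    A0 <- pi * r^2
    sum(A0) * (vs$length[i] / ncell)
  }, numeric(1))) * 1e6

  vcor0 <- if (coro_enabled) sum(vapply(coro, function(d) sum(d$V_init),
                                        numeric(1))) else 0
  vch <- sum(vapply(model$chambers, function(x) x$volume, numeric(1)))
  remaining <- model$blood$total_volume - v1d - vch - vcor0
  if (remaining <= 0) stop("total blood volume too small for the 1D tree and chambers")
  alloc <- distribute_blood_volume(remaining,
                                   stats::setNames(comps$volume / sum(comps$volume),
                                                   comps$id))

  # regulation block (fill defaults when disabled)
  reg <- model$regulation
  if (is.null(reg)) reg <- list(enabled = FALSE)
  reg$enabled <- isTRUE(reg$enabled) && regulation_on
  if (!reg$enabled) reg <- list(enabled = FALSE)

  # afferent nodes: aortic arch site + distal node of every carotid
  ncells <- vapply(seq_len(nv), function(i)
    max(2, ceiling(vs$length[i] / numerics$dx)), numeric(1))
  cell_of <- function(pos, ncell) {
    as.integer(max(0, min(ncell - 1, floor(pos * ncell))))
  }
  aff <- list()
  if (!is.null(model$sites$aortic_arch)) {
    sv <- vidx(model$sites$aortic_arch$vessel)
    aff[[1]] <- c(sv, cell_of(model$sites$aortic_arch$position, ncells[sv + 1]))
  }
  for (i in which(grepl("carotid", vs$name))) {
    aff[[length(aff) + 1]] <- c(i - 1L, as.integer(ncells[i] - 1))
  }
  if (!length(aff)) aff[[1]] <- c(root - 1L, 0L)

  cbf_vessels <- which(vapply(seq_len(nv), function(i) {
    tc <- term_comp[i]
    tc >= 0 && comps$region[tc + 1] == "head" && comps$kind[tc + 1] == "arteriole"
  }, logical(1))) - 1L

  sites <- lapply(model$sites, function(s) {
    sv <- vidx(s$vessel)
    c(sv, cell_of(s$position, ncells[sv + 1]))
  })

  list(
    blood = list(density = rho, viscosity = model$blood$viscosity,
                 chi = model$blood$chi_profile %||% 1.1,
                 zeta = model$blood$zeta_profile %||% 9,
                 total_volume = model$blood$total_volume),
    pref_pa = pref_pa,
    dx = numerics$dx,
    vessels = vlist,
    junctions = junctions,
    root_vessel = root - 1L,
    term_Z = term_Z,
    compartments = clist,
    chambers = model$chambers,
    cardiac_valves = model$cardiac_valves,
    venous_valves = vv_list,
    coronary = coro,
    coro_enabled = coro_enabled,
    regulation = reg,
    heart_rate = model$heart_rate,
    intrathoracic = model$intrathoracic,
    aff_nodes = aff,
    cbf_vessels = as.integer(cbf_vessels),
    sites = sites,
    p_init = comps$p_init,
    volume_alloc = as.numeric(alloc),
    alpha0 = 0,
    p_init_1d_pa = mmHg_to_Pa(p1d)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.build_segments <- function(sched, numerics) {
  hold <- function(minb, maxb, capture = FALSE) {
    list(type = "hold", min_beats = minb, max_beats = maxb,
         steady_tol = numerics$steady_tol,
         steady_beats = numerics$steady_beats, capture = capture)
  }
  segs <- list(hold(numerics$pre_min_beats, numerics$pre_max_beats,
                    capture = TRUE))
  if (sched$alpha_start > 0) {
    segs <- c(segs, list(
      list(type = "ramp", alpha_end = sched$alpha_start,
           rate = numerics$ascent_rate),
      hold(numerics$post_min_beats, numerics$post_max_beats)))
  }
  if (sched$alpha_end != sched$alpha_start) {
    segs <- c(segs, list(
      list(type = "ramp", alpha_end = sched$alpha_end,
           rate = sched$mean_rate),
      hold(numerics$post_min_beats, numerics$post_max_beats)))
  }
  segs
}

#' Run a posture-change protocol on a closed-loop model
#'
#' Runs the coupled 1D-0D system: a supine pre-tilt phase held until a
#' periodic steady state (beat-to-beat variation of beat-averaged MAP
#' and RR below \code{steady_tol} for \code{steady_beats} consecutive
#' beats), automatic capture of the regulation targets (supine mean
#' aortic-carotid pressure, supine mean right-atrial pressure, supine
#' mean cerebral blood flow), the cosinusoidal tilt ramp(s), and a
#' post-tilt phase held until steady again. Tilt-down schedules are
#' preceded by a tilt-up at \code{ascent_rate} and an intermediate
#' steady state.
#'
#' @param model a \code{network_model} from [load_network()].
#' @param sched a [tilt_schedule()]; a supine-only protocol is
#'   \code{tilt_schedule(0, 0, 1)}.
#' @param numerics a [sim_control()] list.
#' @param regulation_on logical; disable to run the unregulated plant.
#' @param coronary_on overrides the config coronary feature flag.
#' @return A \code{simulation_record}: output time grid (\code{time}),
#'   a signals matrix with named columns (site pressures/flows, chamber
#'   pressures/volumes, compartment pressures/volumes/flows, valve
#'   states, regulation state, posture, total volume), the per-beat
#'   table (\code{beats}), phase boundary times, captured regulation
#'   targets and metadata.
#' @export
run_protocol <- function(model, sched, numerics = sim_control(),
                         regulation_on = TRUE, coronary_on = NULL) {
  stopifnot(inherits(model, "network_model"), inherits(sched, "tilt_schedule"))
  ml <- .prepare_model(model, numerics, regulation_on, coronary_on)
  segs <- .build_segments(sched, numerics)
  res <- cpp_run_sim(ml, segs, list(dt = numerics$dt,
                                    out_dt = numerics$out_dt,
                                    cfl_every = numerics$cfl_every))
  sig <- res$signals
  beats <- data.frame(t = res$beat_times, RR = res$beat_RR,
                      map_root = res$beat_map, sv = res$beat_sv,
                      plv_mean = res$beat_plv, alpha = res$beat_alpha)
  structure(list(
    time = sig[, "time"],
    signals = sig,
    beats = beats,
    phase_times = res$phase_times,
    t_capture = res$t_capture,
    targets = res$targets,
    max_junction_resid = res$max_junction_resid,
    segments = segs,
    schedule = sched,
    numerics = numerics,
    regulation_on = regulation_on,
    model_name = model$name,
    model_version = model$model_version
  ), class = "simulation_record")
}

#' Beat boundaries of a simulation record
#'
#' Beat boundaries are the logged ventricular activation onsets (not
#' derived from pressure), so they remain valid during tilt transients.
#'
#' @param record a \code{simulation_record}.
#' @return Numeric vector of beat onset times, s.
#' @export
detect_beats <- function(record) {
  record$beats$t
}

#' @export
print.simulation_record <- function(x, ...) {
  cat("simulation_record:", x$model_name, "\n")
  cat(sprintf("  %.1f s simulated, %d beats, %d output samples\n",
              max(x$time), nrow(x$beats), length(x$time)))
  cat(sprintf("  tilt %g -> %g deg at %g deg/s\n", x$schedule$alpha_start,
              x$schedule$alpha_end, x$schedule$mean_rate))
  invisible(x)
}

# ------------------------------------------------------------------
# 1D solver drivers (single vessel / bifurcation fixtures)
# ------------------------------------------------------------------

#' Run a single 1D vessel experiment
#'
#' Drives one uniform or tapered vessel with configurable end
#' conditions; used for the wave-speed, hydrostatic-equilibrium and
#' reflection verification of the 1D scheme.
#'
#' @param length,radius vessel geometry, m (uniform radius).
#' @param wave_speed_ref reference pulse wave speed, m/s.
#' @param inlet,outlet boundary condition lists: \code{list(type =
#'   "closed")}, \code{list(type = "flow", t = , Q = )} (inlet),
#'   \code{list(type = "pressure", p = )}, \code{list(type =
#'   "impedance", p = , Z = )} or \code{list(type = "matched", p = )}
#'   (outlet). Pressures in Pa, flows m^3/s.
#' @param dt,dx numerical resolution (s, m).
#' @param t_end simulated time, s.
#' @param alpha tilt angle, rad; \code{proj} the axis projection.
#' @param p_init initial pressure, Pa (relative to the reference state).
#' @param gamma_visc wall viscoelastic coefficient, Pa s m.
#' @param proj longitudinal projection in [-1, 1].
#' @param rho,mu blood density and viscosity.
#' @param record_every store every n-th step.
#' @return List with \code{time}, node positions \code{x}, and matrices
#'   \code{A}, \code{Q}, \code{p} (rows = times).
#' @export
run_vessel_1d <- function(length, radius, wave_speed_ref,
                          inlet = list(type = "closed"),
                          outlet = list(type = "closed"),
                          dt = 1e-4, dx = 0.025, t_end = 1,
                          alpha = 0, proj = 0, p_init = 0,
                          gamma_visc = 0,
                          rho = tiltsim_constants$rho_blood,
                          mu = tiltsim_constants$mu_blood,
                          record_every = 10) {
  A0 <- pi * radius^2
  beta <- 2 * rho * wave_speed_ref^2 * sqrt(A0)
  spec <- list(name = "fixture", length = length, r_prox = radius,
               r_dist = radius, beta = beta, gamma_visc = gamma_visc,
               proj = proj, dx = dx, pref = 0)
  nsteps <- ceiling(t_end / dt)
  cpp_run_vessel(spec, inlet, outlet, dt, nsteps, alpha, p_init,
                 as.integer(record_every), rho, mu, 1.1, 9)
}

#' Advance a 1D vessel state by a number of time steps
#'
#' Thin contract-level wrapper over the same compiled kernel as
#' [run_vessel_1d()], returning only the final state.
#'
#' @inheritParams run_vessel_1d
#' @param nsteps number of time steps.
#' @return List with final \code{A}, \code{Q}, \code{p} node vectors.
#' @export
advance_vessel <- function(length, radius, wave_speed_ref, nsteps,
                           dt = 1e-4, dx = 0.025,
                           inlet = list(type = "closed"),
                           outlet = list(type = "closed"),
                           alpha = 0, proj = 0, p_init = 0,
                           gamma_visc = 0,
                           rho = tiltsim_constants$rho_blood,
                           mu = tiltsim_constants$mu_blood) {
  A0 <- pi * radius^2
  beta <- 2 * rho * wave_speed_ref^2 * sqrt(A0)
  spec <- list(name = "fixture", length = length, r_prox = radius,
               r_dist = radius, beta = beta, gamma_visc = gamma_visc,
               proj = proj, dx = dx, pref = 0)
  out <- cpp_run_vessel(spec, inlet, outlet, dt, as.integer(nsteps), alpha,
                        p_init, as.integer(max(nsteps, 1)), rho, mu, 1.1, 9)
  n <- nrow(out$A)
  list(A = out$A[n, ], Q = out$Q[n, ], p = out$p[n, ], x = out$x)
}

#' Run a bifurcation experiment
#'
#' A parent vessel splits into \code{n_children} identical children
#' (or one identical continuation vessel); junction coupling enforces
#' mass and total-pressure conservation. Children end in matched
#' (non-reflecting) terminations.
#'
#' @param parent,child lists with \code{length}, \code{radius},
#'   \code{wave_speed_ref}.
#' @param n_children number of identical children.
#' @param inlet inlet boundary list (see [run_vessel_1d()]).
#' @param dt,dx,t_end numerics.
#' @param p_init initial pressure, Pa.
#' @param rho,mu blood properties.
#' @param record_every store every n-th step.
#' @return List with \code{time}, matrix \code{mid} of mid-vessel
#'   (p, Q) pairs (parent first), and the per-sample relative junction
#'   \code{mass_defect}.
#' @export
run_bifurcation_1d <- function(parent, child, n_children = 2,
                               inlet = list(type = "closed"),
                               dt = 5e-5, dx = 0.02, t_end = 0.5,
                               p_init = 0,
                               rho = tiltsim_constants$rho_blood,
                               mu = tiltsim_constants$mu_blood,
                               record_every = 5) {
  mk <- function(g) {
    A0 <- pi * g$radius^2
    list(name = "fixture", length = g$length, r_prox = g$radius,
         r_dist = g$radius,
         beta = 2 * rho * g$wave_speed_ref^2 * sqrt(A0),
         gamma_visc = 0, proj = 0, dx = dx, pref = 0)
  }
  children <- rep(list(mk(child)), n_children)
  cpp_run_bifurcation(mk(parent), children, inlet, 0, dt,
                      as.integer(ceiling(t_end / dt)), p_init,
                      as.integer(record_every), rho, mu, 1.1, 9)
}
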