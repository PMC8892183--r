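# Derived hemodynamic parameters, waveform analytics, hydrostatic
# decomposition and ensemble averaging.

#' Per-beat hemodynamic metrics from a simulation record
#'
#' For every beat (ventricular activation onset to the next):
#' \itemize{
#'   \item MAP / SBP / DBP / pulse pressure at the requested arterial
#'     sites (time average / max / min over the beat);
#'   \item HR (from the commanded RR), SV (integral of aortic-valve
#'     flow), CO = SV x HR, TPR = central MAP / CO;
#'   \item CVP (beat-mean right-atrial pressure);
#'   \item SW, the left-ventricular pressure-volume loop area (shoelace
#'     formula over the beat's (V, p) samples);
#'   \item TTI = 60 x beat-mean LV pressure (mean LV pressure times RR
#'     times beats per minute);
#'   \item CBF (beat-mean carotid + vertebral flow);
#'   \item V_cp, the cardio-pulmonary blood volume (four chambers plus
#'     pulmonary artery and vein compartments) and V_L, the total legs
#'     vascular volume.
#' }
#'
#' @param record a \code{simulation_record}.
#' @param sites character vector of site names (columns
#'   \code{p_<site>}) to compute pressure statistics for.
#' @param central_site site used for MAP in the TPR ratio.
#' @return A data.frame with one row per complete beat.
#' @export
beat_metrics <- function(record,
                         sites = c("aortic_root", "aortic_arch",
                                   "brachial_mid", "tibial_distal"),
                         central_site = "aortic_root") {
  sig <- record$signals
  tt <- record$time
  bt <- record$beats$t
  if (length(bt) < 2) stop("beat_metrics: need at least one complete beat")
  for (s in sites) {
    if (!(paste0("p_", s) %in% colnames(sig))) {
      stop(sprintf("beat_metrics: configuration error, unknown site '%s'", s),
           call. = FALSE)
    }
  }
  nb <- length(bt) - 1
  idx <- findInterval(tt, bt)
  out <- data.frame(t = bt[seq_len(nb)], RR = diff(bt))
  out$HR <- 60 / out$RR
  vcp_cols <- intersect(c("V_ra", "V_rv", "V_la", "V_lv",
                          "V_pulmonary_artery", "V_pulmonary_vein"),
                        colnames(sig))
  vl_cols <- grep("^V_legs", colnames(sig), value = TRUE)
  agg <- function(x, f) vapply(seq_len(nb), function(b) f(x[idx == b]),
                               numeric(1))
  for (s in sites) {
    p <- sig[, paste0("p_", s)]
    out[[paste0("MAP_", s)]] <- agg(p, mean)
    out[[paste0("SBP_", s)]] <- agg(p, max)
    out[[paste0("DBP_", s)]] <- agg(p, min)
    out[[paste0("PP_", s)]] <- out[[paste0("SBP_", s)]] - out[[paste0("DBP_", s)]]
  }
  out$SV <- agg(sig[, "q_aortic"], mean) * out$RR
  out$CO <- out$SV * out$HR / 1000            # l/min
  out$CVP <- agg(sig[, "p_ra"], mean)
  out$TPR <- out[[paste0("MAP_", central_site)]] / (out$SV * out$HR / 60)
  plv <- agg(sig[, "p_lv"], mean)
  out$TTI <- plv * 60
  out$SW <- vapply(seq_len(nb), function(b) {
    k <- which(idx == b)
    pv_loop_area(sig[k, "V_lv"], sig[k, "p_lv"])
  }, numeric(1))
  if ("cbf" %in% colnames(sig)) out$CBF <- agg(sig[, "cbf"], mean)
  out$V_cp <- agg(rowSums(sig[, vcp_cols, drop = FALSE]), mean)
  if (length(vl_cols)) out$V_L <- agg(rowSums(sig[, vl_cols, drop = FALSE]), mean)
  out$alpha <- agg(sig[, "alpha"], mean)
  out
}

#' Area of a pressure-volume loop (shoelace formula)
#'
#' @param V,p vertex coordinates of the loop in beat order (ml, mmHg);
#'   the polygon is closed automatically.
#' @return Absolute loop area, mmHg ml.
#' @export
pv_loop_area <- function(V, p) {
  n <- length(V)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(V * p[j] - V[j] * p)) / 2
}

#' Remove the heart-referenced hydrostatic column from a pressure change
#'
#' \eqn{\Delta p^* = \Delta p - \rho g z \sin\alpha} (in mmHg), where z
#' is the site's longitudinal position measured from the right atrium,
#' feetward positive. The round trip
#' \code{delta_p_star + hydrostatic column = delta_p} is exact.
#'
#' @param delta_p pressure change at the site, mmHg.
#' @param z_site site position, m (feetward positive, 0 at the heart).
#' @param alpha tilt angle, degrees.
#' @param rho blood density, kg/m^3.
#' @return \code{delta_p_star} in mmHg.
#' @export
hydrostatic_decomposition <- function(delta_p, z_site, alpha,
                                      rho = tiltsim_constants$rho_blood) {
  delta_p - Pa_to_mmHg(rho * tiltsim_constants$g * z_site *
                         sin(deg_to_rad(alpha)))
}

#' Ensemble-average waveform over beats and sources
#'
#' Each beat is resampled onto \code{n_points} points of normalized
#' time (fraction of its RR duration), so the result is invariant to
#' stretching a beat in time. With grouped input (a list of sources,
#' each a list of beats) the SD band combines within-source and
#' between-source variability by the law of total variance. Optionally
#' each source is rescaled by its time-averaged mean before averaging.
#'
#' @param beats either a list of numeric vectors (one per beat) or a
#'   list of such lists (one per source/subject).
#' @param n_points resampling grid size.
#' @param rescale logical: divide each source's beats by the source's
#'   overall mean value.
#' @return List with \code{phase} (normalized time), \code{mean} and
#'   \code{sd}.
#' @export
ensemble_waveform <- function(beats, n_points = 200, rescale = FALSE) {
  if (!length(beats)) stop("ensemble_waveform: empty input", call. = FALSE)
  grouped <- is.list(beats[[1]])
  grid <- seq(0, 1, length.out = n_points)
  resample <- function(y) {
    ny <- length(y)
    if (ny < 2) return(rep(y, n_points))
    stats::approx(seq(0, 1, length.out = ny), y, xout = grid)$y
  }
  if (!grouped) beats <- list(beats)
  src_mean <- list(); src_var <- list()
  for (s in seq_along(beats)) {
    m <- do.call(rbind, lapply(beats[[s]], resample))
    if (rescale) m <- m / mean(m)
    src_mean[[s]] <- colMeans(m)
    src_var[[s]] <- if (nrow(m) > 1) {
      apply(m, 2, stats::var) * (nrow(m) - 1) / nrow(m)
    } else rep(0, n_points)
  }
  M <- do.call(rbind, src_mean)
  mu <- colMeans(M)
  between <- if (nrow(M) > 1) apply(M, 2, stats::var) * (nrow(M) - 1) / nrow(M)
  else rep(0, n_points)
  within <- colMeans(do.call(rbind, src_var))
  list(phase = grid, mean = mu, sd = sqrt(within + between))
}

# beats of one signal cut from a record between two times
.record_beats <- function(record, column, t_from, t_to) {
  bt <- record$beats$t
  keep <- which(bt >= t_from & bt <= t_to)
  keep <- keep[keep < length(bt)]
  lapply(keep, function(b) {
    k <- record$time >= bt[b] & record$time < bt[b + 1]
    record$signals[k, column]
  })
}

#' Beat-averaged steady-state summary of a record phase
#'
#' Averages [beat_metrics()] over the last \code{n_beats} complete
#' beats before \code{t_end} (default: the end of the record).
#'
#' @param record a \code{simulation_record}.
#' @param t_end time bound, s.
#' @param n_beats number of beats to average.
#' @param ... passed to [beat_metrics()].
#' @return Named numeric vector of steady-state parameters.
#' @export
steady_state_metrics <- function(record, t_end = NULL, n_beats = 10, ...) {
  bm <- beat_metrics(record, ...)
  if (!is.null(t_end)) bm <- bm[bm$t + bm$RR <= t_end, , drop = FALSE]
  if (!nrow(bm)) stop("steady_state_metrics: no complete beats in window")
  bm <- utils::tail(bm, n_beats)
  colMeans(bm[vapply(bm, is.numeric, logical(1))])
}

#' Supine vs tilted steady-state comparison report
#'
#' Absolute values and relative changes \code{(tilt - supine)/supine}
#' for the main hemodynamic parameters, with central and brachial MAP
#' reported separately. If a reference-range table is supplied (columns
#' \code{param}, \code{rel_lo}, \code{rel_hi}, relative changes in
#' percent), a pass/fail flag is added.
#'
#' @param record record containing the tilted steady state (its final
#'   phase is used).
#' @param supine_record record (or the same record) whose pre-tilt
#'   phase provides the supine reference.
#' @param n_beats beats averaged on each side.
#' @param reference optional reference-range data.frame, e.g.
#'   [reference_ranges()].
#' @return data.frame with columns \code{param}, \code{supine},
#'   \code{tilt}, \code{rel_change_pct} (and \code{in_range}).
#' @export
steady_state_report <- function(record, supine_record = record,
                                n_beats = 10, reference = NULL) {
  sup <- steady_state_metrics(supine_record,
                              t_end = supine_tilt_start(supine_record),
                              n_beats = n_beats)
  tlt <- steady_state_metrics(record, n_beats = n_beats)
  common <- intersect(names(sup), names(tlt))
  common <- setdiff(common, c("t", "alpha"))
  df <- data.frame(param = common, supine = sup[common], tilt = tlt[common],
                   row.names = NULL)
  df$rel_change_pct <- 100 * (df$tilt - df$supine) / df$supine
  if (!is.null(reference)) {
    m <- match(df$param, reference$param)
    df$in_range <- ifelse(is.na(m), NA,
                          df$rel_change_pct >= reference$rel_lo[m] &
                            df$rel_change_pct <= reference$rel_hi[m])
  }
  df
}

#' Time at which the first tilt ramp of a record starts
#'
#' @param record a \code{simulation_record}.
#' @return Start time of the first ramp segment (end of the supine
#'   phase), or the record end for supine-only protocols.
#' @export
supine_tilt_start <- function(record) {
  types <- vapply(record$segments, function(s) s$type, character(1))
  k <- which(types == "ramp")
  if (!length(k)) return(max(record$time))
  record$phase_times[k[1]]
}

#' Literature reference ranges for the 70-degree head-up tilt response
#'
#' Relative steady-state changes (percent, tilted vs supine) compiled
#' from the clinical literature on passive 70-degree head-up tilt;
#' shipped as static reference data for [steady_state_report()].
#'
#' @return data.frame with \code{param}, \code{rel_lo}, \code{rel_hi}.
#' @export
reference_ranges <- function() {
  utils::read.csv(system.file("extdata", "reference_ranges_hut70.csv",
                              package = "tiltsim"), stringsAsFactors = FALSE)
}
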