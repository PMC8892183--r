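# Plain-text exports of simulation records.

#' Export a simulation record to CSV and a JSON summary
#'
#' Writes \code{signals.csv} (the sampled signal matrix),
#' \code{beats.csv} (per-beat metrics) and \code{summary.json}
#' (beat-averaged parameters of the supine and final steady states,
#' the tilt schedule, captured regulation targets and metadata).
#'
#' @param record a \code{simulation_record}.
#' @param dir output directory (created if missing).
#' @param signals logical: write the full signal matrix (can be large).
#' @return The directory path, invisibly.
#' @export
export_record <- function(record, dir, signals = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (signals) {
    utils::write.csv(as.data.frame(record$signals),
                     file.path(dir, "signals.csv"), row.names = FALSE)
  }
  bm <- beat_metrics(record)
  utils::write.csv(bm, file.path(dir, "beats.csv"), row.names = FALSE)
  sup <- as.list(steady_state_metrics(record,
                                      t_end = supine_tilt_start(record)))
  fin <- as.list(steady_state_metrics(record))
  summary <- list(
    model = record$model_name,
    model_version = record$model_version,
    schedule = unclass(record$schedule),
    regulation_on = record$regulation_on,
    targets = record$targets,
    supine_steady = sup,
    final_steady = fin,
    numerics = record$numerics
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export per-site pressure/flow time series
#'
#' @param record a \code{simulation_record}.
#' @param path CSV output path.
#' @param sites site names (defaults to every recorded site).
#' @return \code{path}, invisibly.
#' @export
export_sites_csv <- function(record, path, sites = NULL) {
  cn <- colnames(record$signals)
  if (is.null(sites)) {
    keep <- c("time", "alpha", grep("^(p|q)_", cn, value = TRUE))
  } else {
    keep <- c("time", "alpha", paste0("p_", sites), paste0("q_", sites))
  }
  keep <- intersect(keep, cn)
  utils::write.csv(as.data.frame(record$signals[, keep, drop = FALSE]),
                   path, row.names = FALSE)
  invisible(path)
}
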