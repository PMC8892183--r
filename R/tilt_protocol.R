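# Posture schedule: cosinusoidal tilt ramps at a configurable mean rate.

#' Build a tilt schedule
#'
#' The tilt angle follows a cosinusoidal ramp whose mean slope equals
#' \code{mean_rate}, so the ramp duration is
#' \code{|alpha_end - alpha_start| / mean_rate}; the ramp is C1 at both
#' endpoints. Tilt-down schedules simply swap start and end angles.
#'
#' @param alpha_start,alpha_end start and end tilt angles, degrees in
#'   [0, 90].
#' @param mean_rate mean tilting rate, deg/s (> 0).
#' @param t_start ramp start time, s.
#' @param pre_hold,post_hold steady-hold durations before and after the
#'   ramp, s (informational; the engine may extend them until steady
#'   state).
#' @return An object of class \code{tilt_schedule}.
#' @export
tilt_schedule <- function(alpha_start, alpha_end, mean_rate,
                          t_start = 0, pre_hold = 60, post_hold = 120) {
  stopifnot(mean_rate > 0,
            alpha_start >= 0, alpha_start <= 90,
            alpha_end >= 0, alpha_end <= 90)
  ramp <- abs(alpha_end - alpha_start) / mean_rate
  structure(list(alpha_start = alpha_start, alpha_end = alpha_end,
                 mean_rate = mean_rate, t_start = t_start,
                 ramp_duration = ramp, pre_hold = pre_hold,
                 post_hold = post_hold),
            class = "tilt_schedule")
}

#' Tilt angle at a given time
#'
#' @param t time, s (vectorized).
#' @param sched a [tilt_schedule()].
#' @return Tilt angle in degrees: \code{alpha_start} before the ramp,
#'   the cosinusoidal transition
#'   \eqn{\alpha(t) = \alpha_0 + (\alpha_1 - \alpha_0)
#'        (1 - \cos(\pi (t - t_0)/T))/2}
#'   during it, \code{alpha_end} after.
#' @export
tilt_angle <- function(t, sched) {
  a0 <- sched$alpha_start
  a1 <- sched$alpha_end
  Tr <- sched$ramp_duration
  if (Tr <= 0) return(rep(a1, length(t)))
  s <- (t - sched$t_start) / Tr
  s <- pmin(pmax(s, 0), 1)
  a0 + (a1 - a0) * (1 - cos(pi * s)) / 2
}

#' Build a list of tilt schedules from a sweep request
#'
#' Supports the rate sweep \{35, 8, 4, 2.5, 1.4\} deg/s and angles
#' \{30, 70, 90\} used in the tilt experiments, as well as arbitrary
#' combinations.
#'
#' @param angles target tilt angles, degrees.
#' @param rates mean tilting rates, deg/s (all > 0).
#' @param direction \code{"up"} (supine to tilted) or \code{"down"}.
#' @param t_start,pre_hold,post_hold passed to [tilt_schedule()].
#' @return A list of \code{tilt_schedule} objects, one per
#'   (angle, rate) combination.
#' @export
build_protocol <- function(angles = 70, rates = 4,
                           direction = c("up", "down"),
                           t_start = 0, pre_hold = 60, post_hold = 120) {
  direction <- match.arg(direction)
  if (any(rates <= 0)) stop("build_protocol: tilting rate must be positive",
                            call. = FALSE)
  if (any(rates > 90)) stop("build_protocol: tilting rate above 90 deg/s",
                            call. = FALSE)
  out <- list()
  for (a in angles) {
    for (r in rates) {
      from <- if (direction == "up") 0 else a
      to <- if (direction == "up") a else 0
      out[[length(out) + 1]] <-
        tilt_schedule(from, to, r, t_start, pre_hold, post_hold)
    }
  }
  out
}
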