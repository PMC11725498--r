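#' Tether twist bookkeeping
#'
#' The active commutator cancels tether twist using only the animal's
#' absolute heading — no torque sensing. `twist_state()` tracks the
#' cumulative (unwrapped) heading, the cumulative commanded motor angle,
#' and their difference in turns, which is the twist currently stored in
#' the tether. The identity
#' `residual_twist_turns == (unwrapped_heading - motor_angle) / 360`
#' holds at all times.
#'
#' @param heading_deg Initial wrapped heading in \[-180, 180).
#' @return A `twist_state` object.
#' @export
twist_state <- function(heading_deg = 0) {
  if (heading_deg < -180 || heading_deg >= 180) {
    stop_tethersim("domain", "heading must lie in [-180, 180)")
  }
  structure(list(unwrapped_heading_deg = heading_deg,
                 motor_angle_deg = 0,
                 residual_twist_turns = heading_deg / 360,
                 last_wrapped_heading_deg = heading_deg,
                 armed = TRUE),
            class = "twist_state")
}

#' Shortest-path angle unwrapping step
#'
#' Signed heading change between consecutive wrapped readings, mapped to
#' (-180, 180]. Valid while the animal turns less than half a revolution
#' per sample — guaranteed at any realistic sensor rate. Deltas within
#' 1 degree of the +/-180 ambiguity trigger a warning, since they signal a
#' violated assumption.
#'
#' @param prev_wrapped_deg,new_wrapped_deg Wrapped headings in
#'   \[-180, 180) (vectorized).
#' @return Signed delta in degrees, in (-180, 180].
#' @export
unwrap_step <- function(prev_wrapped_deg, new_wrapped_deg) {
  bad <- prev_wrapped_deg < -180 | prev_wrapped_deg >= 180 |
    new_wrapped_deg < -180 | new_wrapped_deg >= 180
  if (any(bad)) stop_tethersim("domain", "headings must lie in [-180, 180)")
  d <- new_wrapped_deg - prev_wrapped_deg
  d <- ifelse(d > 180, d - 360, ifelse(d <= -180, d + 360, d))
  if (any(abs(abs(d) - 180) < 1)) {
    warning("heading step near 180 degrees: shortest-path unwrapping ",
            "assumption may be violated")
  }
  d
}

#' Advance twist state with a new heading reading
#'
#' Applies [unwrap_step()] to accumulate heading and recomputes the
#' residual twist. Pure function of its inputs.
#'
#' @param state A [twist_state()].
#' @param new_wrapped_heading_deg New wrapped heading in \[-180, 180).
#' @return Updated `twist_state`.
#' @export
update_twist <- function(state, new_wrapped_heading_deg) {
  d <- unwrap_step(state$last_wrapped_heading_deg, new_wrapped_heading_deg)
  state$unwrapped_heading_deg <- state$unwrapped_heading_deg + d
  state$last_wrapped_heading_deg <- new_wrapped_heading_deg
  state$residual_twist_turns <-
    (state$unwrapped_heading_deg - state$motor_angle_deg) / 360
  state
}

#' Commutator motor policy
#'
#' When accumulated twist reaches the threshold, command a rotation that
#' cancels it: `sign(residual) * min(|residual| * 360 quantized to the
#' stepper step, max slew)`. Hysteresis: after a command, no new command is
#' issued until the threshold is exceeded again. The policy consumes only
#' heading-derived state — never any torque-like input.
#'
#' @param state A [twist_state()].
#' @param threshold_turns Twist magnitude (turns) that triggers a command
#'   (> 0; default 0.25).
#' @param step_deg Stepper quantization in degrees; must divide 360
#'   (default 1.8).
#' @param max_slew_deg Largest single commanded rotation (default `Inf`).
#' @return List with `command_deg` (0 when idle) and `state` (updated).
#' @export
motor_policy <- function(state, threshold_turns = 0.25, step_deg = 1.8,
                         max_slew_deg = Inf) {
  stopifnot(threshold_turns > 0, step_deg > 0)
  if (abs(360 / step_deg - round(360 / step_deg)) > 1e-9) {
    stop_tethersim("domain", "step_deg must divide 360")
  }
  r <- state$residual_twist_turns
  cmd <- 0
  if (abs(r) >= threshold_turns && state$armed) {
    mag <- min(floor(abs(r) * 360 / step_deg) * step_deg, max_slew_deg)
    cmd <- sign(r) * mag
    state$motor_angle_deg <- state$motor_angle_deg + cmd
    state$residual_twist_turns <-
      (state$unwrapped_heading_deg - state$motor_angle_deg) / 360
    state$armed <- FALSE
  } else if (abs(r) < threshold_turns) {
    state$armed <- TRUE
  }
  list(command_deg = cmd, state = state)
}

#' Run the commutator over a heading series
#'
#' Feeds a wrapped heading series (degrees, \[-180, 180)) through
#' [update_twist()] and [motor_policy()], one sample at a time, and logs
#' residual twist, commands and motor angle.
#'
#' @param heading_deg Wrapped heading series.
#' @param time_s Optional time stamps (defaults to sample index).
#' @inheritParams motor_policy
#' @return Data frame `time_s`, `residual_turns`, `command_deg`,
#'   `motor_angle_deg`, plus attribute `state` (final [twist_state()]).
#' @export
run_commutator <- function(heading_deg, time_s = NULL,
                           threshold_turns = 0.25, step_deg = 1.8,
                           max_slew_deg = Inf) {
  n <- length(heading_deg)
  if (is.null(time_s)) time_s <- seq_len(n) - 1
  if (n == 0L) {
    return(data.frame(time_s = numeric(0), residual_turns = numeric(0),
                      command_deg = numeric(0), motor_angle_deg = numeric(0)))
  }
  if (any(heading_deg < -180 | heading_deg >= 180)) {
    stop_tethersim("domain", "headings must lie in [-180, 180)")
  }
  # vectorized unwrap, sequential policy (hysteresis is stateful)
  d <- diff(heading_deg)
  d <- ifelse(d > 180, d - 360, ifelse(d <= -180, d + 360, d))
  unwrapped <- heading_deg[1] + cumsum(c(0, d))
  motor <- 0; armed <- TRUE
  res_log <- numeric(n); cmd_log <- numeric(n); mot_log <- numeric(n)
  thr <- threshold_turns; stp <- step_deg
  for (i in seq_len(n)) {
    r <- (unwrapped[i] - motor) / 360
    cmd <- 0
    if (abs(r) >= thr && armed) {
      mag <- min(floor(abs(r) * 360 / stp) * stp, max_slew_deg)
      cmd <- sign(r) * mag
      motor <- motor + cmd
      r <- (unwrapped[i] - motor) / 360
      armed <- FALSE
    } else if (abs(r) < thr) {
      armed <- TRUE
    }
    res_log[i] <- r; cmd_log[i] <- cmd; mot_log[i] <- motor
  }
  final <- twist_state()
  final$unwrapped_heading_deg <- unwrapped[n]
  final$motor_angle_deg <- motor
  final$residual_twist_turns <- (unwrapped[n] - motor) / 360
  final$last_wrapped_heading_deg <- heading_deg[n]
  final$armed <- armed
  out <- data.frame(time_s = time_s, residual_turns = res_log,
                    command_deg = cmd_log, motor_angle_deg = mot_log)
  attr(out, "state") <- final
  out
}
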