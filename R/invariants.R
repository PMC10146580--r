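#' Optical speed of the ground
#'
#' Angular scrolling rate of the ground texture across the visual field of an
#' agent translating at forward speed `vx` at altitude `z`:
#' \deqn{\omega = \dot{x} / z.}
#' The closer the agent is to the ground, the faster the ground sweeps its
#' visual field. `omega` is a low-order variable: many speed--altitude couples
#' give the same value.
#'
#' @param vx Forward speed (cm/s).
#' @param z Altitude above the ground (cm); must be strictly positive.
#' @return Optical speed (rad/s). Arguments are recycled.
#' @seealso [osrc()], [relative_osrc()]
#' @export
#' @examples
#' optical_speed(50, 25) # 2 rad/s
optical_speed <- function(vx, z) {
  check_altitude(z)
  vx / z
}

#' Optical speed rate of change (OSRC)
#'
#' Temporal derivative of the optical speed of the ground,
#' \deqn{\dot\omega = (z \ddot{x} - \dot{x}\dot{z}) / z^2.}
#' For constant forward speed (`ax = 0`), a positive OSRC always signals a loss
#' of altitude and a negative OSRC a gain: it is a high-order variable that
#' *specifies* the altitude change.
#'
#' @param vx Forward speed (cm/s).
#' @param ax Forward acceleration (cm/s^2).
#' @param z Altitude (cm), strictly positive.
#' @param vz Vertical speed (cm/s).
#' @return OSRC (rad/s^2).
#' @export
osrc <- function(vx, ax, z, vz) {
  check_altitude(z)
  (z * ax - vx * vz) / z^2
}

#' Relative OSRC
#'
#' Ratio \eqn{\dot\omega/\omega}. For unaccelerated forward flight this equals
#' \eqn{-\dot{z}/z}, the relative altitude-loss rate, independently of forward
#' speed: the quantity an agent can null to hold altitude.
#'
#' @param omega_dot OSRC (rad/s^2).
#' @param omega Optical speed (rad/s); must be nonzero.
#' @return Relative rate (1/s).
#' @export
relative_osrc <- function(omega_dot, omega) {
  if (any(omega == 0)) {
    stop("relative OSRC is undefined for omega = 0 (stationary agent)")
  }
  omega_dot / omega
}

#' Splay angle of a ground-parallel line
#'
#' Angle subtended at the vanishing point by the direction of motion and the
#' image of a line parallel to it on the ground, for a line at lateral distance
#' `y_off` from an agent at altitude `z`:
#' \deqn{S = \arctan(y / z).}
#'
#' @param y_off Lateral distance of the line from the agent (cm), non-negative.
#' @param z Altitude (cm), strictly positive.
#' @return Splay angle (rad), in \[0, pi/2).
#' @export
#' @examples
#' splay_angle(12.5, 14) # rods at the floor-wall junction, entrance height
splay_angle <- function(y_off, z) {
  check_altitude(z)
  if (any(y_off < 0)) stop("y_off must be non-negative")
  atan(y_off / z)
}

#' Splay angle rate of change (SARC)
#'
#' Temporal derivative of the splay angle:
#' \deqn{\dot{S} = (-\dot{z}/z)\cos S \sin S + (\dot{y}/z)\cos^2 S.}
#' With no lateral motion, a loss of altitude gives a positive SARC, a gain a
#' negative one. `vy_rel` is the lateral velocity of the splay line relative to
#' the agent, so that a moving line stimulates SARC in a stationary agent.
#'
#' @param S Splay angle (rad).
#' @param vz Vertical speed (cm/s).
#' @param z Altitude (cm), strictly positive.
#' @param vy_rel Agent-relative lateral speed of the line (cm/s).
#' @return SARC (rad/s).
#' @export
sarc <- function(S, vz, z, vy_rel = 0) {
  check_altitude(z)
  (-vz / z) * cos(S) * sin(S) + (vy_rel / z) * cos(S)^2
}

#' Relative SARC
#'
#' Ratio \eqn{2\dot{S}/\sin(2S)}. With no lateral motion this equals
#' \eqn{-\dot{z}/z}, the same relative altitude-loss rate as the relative OSRC:
#' the two invariants share one behaviorally useful quantity.
#'
#' @param S_dot SARC (rad/s).
#' @param S Splay angle (rad); `sin(2S)` must not vanish.
#' @return Relative rate (1/s).
#' @export
relative_sarc <- function(S_dot, S) {
  s2 <- sin(2 * S)
  if (any(abs(s2) < 1e-9)) {
    stop("relative SARC is undefined near S = 0 or S = pi/2")
  }
  2 * S_dot / s2
}

#' Finite-difference derivative of a uniformly sampled series
#'
#' Central differences on interior points, one-sided differences at the two
#' ends; the output has the same length as the input. Used to extract OSRC and
#' SARC numerically from discrete trajectories.
#'
#' @param x Numeric series sampled at constant spacing.
#' @param dt Sampling interval (s), positive.
#' @return Derivative series of `length(x)`.
#' @export
finite_difference_rates <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for finite differences")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

# altitude domain guard shared by the optical primitives
check_altitude <- function(z) {
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("altitude z must be strictly positive (agent above the ground)")
  }
  invisible(z)
}

#' Kinematic state of the agent
#'
#' Instantaneous position/velocity/acceleration in tunnel coordinates: `x`
#' longitudinal (cm), `y` signed lateral offset from the midline (cm), `z`
#' altitude (cm), and their derivatives. Forward acceleration `ax` is retained
#' so that the OSRC formula can be evaluated in full, although the simulator
#' holds forward speed constant within a flight.
#'
#' @param t Time (s).
#' @param x,y,z Position (cm).
#' @param vx,vy,vz Velocities (cm/s).
#' @param ax Forward acceleration (cm/s^2).
#' @return An object of class `kinematic_state` (a named list).
#' @export
kinematic_state <- function(t = 0, x = 0, y = 0, z = 14,
                            vx = 55, vy = 0, vz = 0, ax = 0) {
  if (z <= 0) stop("altitude z must be strictly positive")
  structure(
    list(t = t, x = x, y = y, z = z, vx = vx, vy = vy, vz = vz, ax = ax),
    class = "kinematic_state"
  )
}
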