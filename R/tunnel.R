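#' Flight tunnel geometry
#'
#' Rectangular tunnel with entrance and exit holes near the floor. Defaults
#' match the experimental tunnel: 220 cm long, 71 cm high, 25 cm wide, holes
#' 14 cm above the floor.
#'
#' @param length,height,width Tunnel dimensions (cm).
#' @param entrance_height Height of the entrance/exit holes above the floor (cm).
#' @return An object of class `tunnel_geometry`.
#' @export
tunnel_geometry <- function(length = 220, height = 71, width = 25,
                            entrance_height = 14) {
  if (any(c(length, height, width, entrance_height) <= 0)) {
    stop("all tunnel dimensions must be positive")
  }
  if (entrance_height >= height) stop("entrance_height must be below the ceiling")
  structure(
    list(length = length, height = height, width = width,
         entrance_height = entrance_height),
    class = "tunnel_geometry"
  )
}

ROD_MODES <- c("parallel", "narrow", "static_converging", "static_diverging",
               "dynamic_converging", "dynamic_diverging")

#' Rod manipulation configuration
#'
#' The tunnel holds one rod along each floor--wall junction; a motorized screw
#' can translate them laterally. Modes:
#' \describe{
#'   \item{parallel}{control; rods at the floor--wall junction (offset width/2).}
#'   \item{narrow}{control; rods static at a reduced offset, the end-state of a
#'     converging trial (default 8.5 cm).}
#'   \item{static_converging / static_diverging}{rods repositioned *between*
#'     flights (splay angle manipulated, its rate of change untouched).}
#'   \item{dynamic_converging / dynamic_diverging}{rods set in motion `onset`
#'     seconds after tunnel entry, *during* the flight (rate of change of splay
#'     manipulated).}
#' }
#'
#' @param mode One of `"parallel"`, `"narrow"`, `"static_converging"`,
#'   `"static_diverging"`, `"dynamic_converging"`, `"dynamic_diverging"`.
#' @param onset Time after entry at which rod motion starts (s), dynamic modes.
#' @param rate Lateral speed of each rod base (cm/s), positive, dynamic modes.
#' @param static_offset Rod base offset from the midline (cm) for the static and
#'   narrow modes. Defaults: 8.5 (narrow, static_converging), width/2
#'   (static_diverging; the physical rods cannot retreat past the walls).
#' @return An object of class `rod_config`.
#' @export
rod_config <- function(mode = "parallel", onset = 2, rate = 2,
                       static_offset = NULL) {
  mode <- match.arg(mode, ROD_MODES)
  if (onset < 0) stop("onset must be non-negative")
  if (grepl("^dynamic", mode) && rate <= 0) stop("rate must be positive for dynamic modes")
  if (is.null(static_offset)) {
    static_offset <- switch(mode,
      narrow = 8.5, static_converging = 8.5, static_diverging = 12.5, 12.5)
  }
  if (static_offset < 0) stop("static_offset must be non-negative")
  structure(
    list(mode = mode, onset = onset, rate = rate, static_offset = static_offset),
    class = "rod_config"
  )
}

#' Ground texture condition
#'
#' The floor sheet is either high-contrast striped (easy access to the ground's
#' optical speed) or mat white (difficult but not impossible access). The
#' accessibility coefficient `os_access` scales how usable the optical-speed
#' channel is; geometry of the optical variables is never affected.
#'
#' @param kind `"striped"` or `"white"`.
#' @param os_access Accessibility coefficient in \[0, 1\]; defaults 1.0
#'   (striped) and 0.1 (white).
#' @return An object of class `texture_condition`.
#' @export
texture_condition <- function(kind = c("striped", "white"), os_access = NULL) {
  kind <- match.arg(kind)
  if (is.null(os_access)) os_access <- if (kind == "striped") 1.0 else 0.1
  if (os_access < 0 || os_access > 1) stop("os_access must lie in [0, 1]")
  structure(list(kind = kind, os_access = os_access),
            class = "texture_condition")
}

#' Lateral rod offset from the midline
#'
#' Static and control modes keep their configured offset at all times. Dynamic
#' modes start at the floor--wall junction (width/2) and translate at `rate`
#' from `onset` on, clamped to \[0.5, width/2\] cm. (A diverging rod therefore
#' stays at the junction: the walls bound its travel; the perceived diverging
#' stimulation is handled by [rod_stim_rate()].)
#'
#' @param t Time since tunnel entry (s), non-negative.
#' @param cfg A [rod_config()].
#' @param geom A [tunnel_geometry()].
#' @return Offset of each rod base from the midline (cm); vectorized over `t`.
#' @export
rod_offset <- function(t, cfg, geom = tunnel_geometry()) {
  if (any(t < 0)) stop("t must be non-negative")
  half <- geom$width / 2
  base <- switch(cfg$mode,
    parallel = half,
    narrow = ,
    static_converging = ,
    static_diverging = cfg$static_offset,
    dynamic_converging = half - cfg$rate * pmax(t - cfg$onset, 0),
    dynamic_diverging = half + cfg$rate * pmax(t - cfg$onset, 0)
  )
  pmin(pmax(rep_len(base, length(t)), 0.5), half)
}

#' Signed splay stimulation rate of the rods
#'
#' Perceived lateral speed of the rods while the motor runs: `+rate` for
#' dynamic convergence, `-rate` for dynamic divergence, 0 otherwise. The motor
#' runs from `onset` for the travel time `(width/2 - 0.5)/rate`, the same
#' duration for both directions, so converging and diverging trials deliver
#' mirror-symmetric stimulation. The sign convention follows the experimental
#' design: convergence is the stimulus that specifies a loss of altitude
#' (perceived SARC > 0).
#'
#' @inheritParams rod_offset
#' @return Signed stimulation speed (cm/s); vectorized over `t`.
#' @export
rod_stim_rate <- function(t, cfg, geom = tunnel_geometry()) {
  if (!grepl("^dynamic", cfg$mode)) return(rep_len(0, length(t)))
  half <- geom$width / 2
  run_time <- (half - 0.5) / cfg$rate
  on <- t >= cfg$onset & t < cfg$onset + run_time
  sgn <- if (cfg$mode == "dynamic_converging") 1 else -1
  ifelse(on, sgn * cfg$rate, 0)
}

#' Perceived optical invariants for an agent state and condition
#'
#' Combines the ground channel (optical speed and OSRC, weighted by the
#' texture's accessibility) and the rod channel (splay angle and SARC) into one
#' perceptual sample.
#'
#' The splay angle is the geometric angle of the rod line nearest the agent,
#' `arctan((offset - y)/z)`. Its rate of change has two parts: the self-motion
#' part from the agent's own vertical and lateral velocity, and a stimulation
#' part injected by moving rods. The stimulation is modeled as a constant
#' relative-rate perturbation of magnitude `rate/(width/2)` (its value at the
#' rods' canonical floor--wall position), signed so that convergence yields a
#' positive perceived SARC and divergence its exact mirror image.
#'
#' @param state A [kinematic_state()]; must lie inside the tunnel with `z > 0`.
#' @param cfg A [rod_config()].
#' @param tex A [texture_condition()].
#' @param geom A [tunnel_geometry()].
#' @param t Time since tunnel entry (s); defaults to `state$t`.
#' @return An object of class `optic_sample`: list with `omega`, `omega_dot`,
#'   `splay`, `splay_dot`, `os_access`.
#' @export
perceived_invariants <- function(state, cfg, tex, geom = tunnel_geometry(),
                                 t = state$t) {
  if (state$z <= 0) stop("agent is at or below the ground")
  off <- rod_offset(t, cfg, geom)
  y_off <- off - state$y
  if (y_off <= 0) stop("agent is laterally outside the rod lines")
  S <- splay_angle(y_off, state$z)
  half <- geom$width / 2
  stim <- rod_stim_rate(t, cfg, geom)
  # self-motion SARC at the geometric splay + symmetric rod stimulation,
  # injected as a relative rate (stim/half) scaled back to an absolute S-dot
  s_dot <- sarc(S, state$vz, state$z, vy_rel = -state$vy) +
    (stim / half) * sin(2 * S) / 2
  structure(
    list(
      omega = optical_speed(state$vx, state$z),
      omega_dot = osrc(state$vx, state$ax, state$z, state$vz),
      splay = S,
      splay_dot = s_dot,
      os_access = tex$os_access
    ),
    class = "optic_sample"
  )
}

#' Read a condition specification from a JSON config file
#'
#' Recognized top-level blocks (all optional): `geometry` (overrides for
#' [tunnel_geometry()]), `rods` (arguments of [rod_config()]), `texture`
#' (arguments of [texture_condition()]).
#'
#' @param path Path to a JSON file.
#' @return List with elements `geom`, `rods`, `texture`.
#' @export
read_condition_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    geom = do.call(tunnel_geometry, as.list(cfg$geometry %||% list())),
    rods = do.call(rod_config, as.list(cfg$rods %||% list())),
    texture = do.call(texture_condition, as.list(cfg$texture %||% list()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.optic_sample <- function(x, ...) {
  cat(sprintf(
    "optic sample: omega %.4g rad/s (access %.2g), OSRC %.4g rad/s^2, splay %.4g rad, SARC %.4g rad/s\n",
    x$omega, x$os_access, x$omega_dot, x$splay, x$splay_dot))
  invisible(x)
}
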