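#' Priority-based altitude controller parameters
#'
#' The controller nulls a perceived relative altitude-loss rate `e` (1/s) built
#' from the two invariants. When the ground's optical speed is easily
#' accessible (`os_access >= c_star`) the relative OSRC is used exclusively;
#' otherwise the two relative rates are blended with weights
#' `w_osrc * os_access` and `w_sarc` (renormalized). The vertical-speed command
#' is `k_gain * e * z`, so a perceived loss of altitude (e > 0) commands a
#' climb.
#'
#' With `safety_mode` on, a descent command that is driven by the SARC channel
#' alone (the OSRC channel does not itself indicate a needed descent) is
#' vetoed, as is any descent below `floor_margin`: of two conflicting
#' invariants, priority goes to the one producing the safer behavior.
#'
#' @param k_gain Gain (1/s) mapping the relative rate to a commanded vertical
#'   speed fraction of altitude.
#' @param c_star Accessibility threshold above which OSRC is used exclusively.
#' @param w_osrc,w_sarc Blending weights (must sum to 1).
#' @param safety_mode Logical; veto SARC-only descent commands.
#' @param floor_margin Altitude (cm) below which all descent commands are
#'   suppressed.
#' @param vz_max Vertical speed cap (cm/s).
#' @param actuator_rate First-order actuator rate (1/s): realized vertical
#'   speed relaxes toward the command at this rate, which keeps the discrete
#'   closed loop stable for gains above 1.
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(k_gain = 2.5, c_star = 0.5,
                              w_osrc = 0.5, w_sarc = 0.5,
                              safety_mode = TRUE, floor_margin = 2,
                              vz_max = 30, actuator_rate = 20) {
  if (k_gain <= 0) stop("k_gain must be positive")
  if (c_star < 0 || c_star > 1) stop("c_star must lie in [0, 1]")
  if (abs(w_osrc + w_sarc - 1) > 1e-9) stop("w_osrc + w_sarc must equal 1")
  if (floor_margin < 0) stop("floor_margin must be non-negative")
  if (vz_max <= 0 || actuator_rate <= 0) stop("vz_max and actuator_rate must be positive")
  structure(
    list(k_gain = k_gain, c_star = c_star, w_osrc = w_osrc, w_sarc = w_sarc,
         safety_mode = isTRUE(safety_mode), floor_margin = floor_margin,
         vz_max = vz_max, actuator_rate = actuator_rate),
    class = "controller_params"
  )
}

#' Simulation configuration for one tunnel traverse
#'
#' @param geom A [tunnel_geometry()].
#' @param rods A [rod_config()].
#' @param texture A [texture_condition()].
#' @param dt Integration step (s); must divide the 10 ms output interval.
#' @param duration Maximum flight duration (s); the flight ends earlier if the
#'   agent reaches the tunnel exit.
#' @param forward_speed Constant forward speed of the flight (cm/s).
#' @param entry_altitude Altitude at tunnel entry (cm).
#' @param altitude_noise_sd Stationary standard deviation (cm) of the AR(1)
#'   altitude jitter overlaid on the controlled path (0 disables it).
#' @param noise_corr_time Correlation time (s) of the jitter.
#' @param pixel_quantize Logical; round output altitudes to the vertical pixel
#'   size of the tracking camera (71/210 cm).
#' @param seed Optional integer seed making the flight reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geom = tunnel_geometry(), rods = rod_config(),
                       texture = texture_condition("white"),
                       dt = 0.01, duration = 4, forward_speed = 55,
                       entry_altitude = 14, altitude_noise_sd = 0,
                       noise_corr_time = 0.05, pixel_quantize = FALSE,
                       seed = NULL) {
  if (dt <= 0 || duration <= 0 || forward_speed <= 0) {
    stop("dt, duration and forward_speed must be positive")
  }
  m <- 0.01 / dt
  if (abs(m - round(m)) > 1e-9) stop("dt must divide the 10 ms output interval")
  if (entry_altitude <= 0 || entry_altitude >= geom$height) {
    stop("entry_altitude must lie inside the tunnel")
  }
  if (altitude_noise_sd < 0) stop("altitude_noise_sd must be non-negative")
  structure(
    list(geom = geom, rods = rods, texture = texture, dt = dt,
         duration = duration, forward_speed = forward_speed,
         entry_altitude = entry_altitude, altitude_noise_sd = altitude_noise_sd,
         noise_corr_time = noise_corr_time,
         pixel_quantize = isTRUE(pixel_quantize), seed = seed),
    class = "sim_config"
  )
}

# scalar core of the control law, shared by command_vertical_speed() and the
# simulation loop; returns the clipped commanded vertical speed (cm/s)
cmd_vz_core <- function(rel_os, rel_sa, os_access, params, z) {
  if (os_access >= params$c_star) {
    e <- rel_os
    sarc_in_use <- FALSE
  } else {
    w1 <- params$w_osrc * os_access
    w2 <- params$w_sarc
    e <- (w1 * rel_os + w2 * rel_sa) / (w1 + w2)
    sarc_in_use <- TRUE
  }
  cmd <- params$k_gain * e * z
  if (cmd < 0) {
    veto <- params$safety_mode &&
      ((sarc_in_use && rel_os >= -1e-12) || z < params$floor_margin)
    if (veto) cmd <- 0
  }
  max(min(cmd, params$vz_max), -params$vz_max)
}

#' Commanded vertical speed from a perceptual sample
#'
#' Applies the priority-based control law to one perceived [optic
#' sample][perceived_invariants()]. Degenerate perceived values (zero optical
#' speed, splay at 0 or pi/2) contribute zero error rather than an error
#' condition.
#'
#' @param perceived An `optic_sample` as returned by [perceived_invariants()].
#' @param params A [controller_params()].
#' @param z Current altitude (cm), strictly positive.
#' @return Commanded vertical speed (cm/s), clipped to `+/- vz_max`.
#' @export
command_vertical_speed <- function(perceived, params = controller_params(), z) {
  if (z <= 0) stop("altitude z must be strictly positive")
  rel_os <- if (is.finite(perceived$omega) && perceived$omega != 0) {
    perceived$omega_dot / perceived$omega
  } else 0
  s2 <- sin(2 * perceived$splay)
  rel_sa <- if (abs(s2) >= 1e-9) 2 * perceived$splay_dot / s2 else 0
  cmd_vz_core(rel_os, rel_sa, perceived$os_access, params, z)
}

#' Simulate one closed-loop flight through the tunnel
#'
#' Explicit time-stepping of the longitudinal/vertical state: `x` advances at
#' the constant forward speed; the vertical speed relaxes (first-order
#' actuator) toward the command of the priority-based control law evaluated on
#' the perceived invariants of the current state. Stationary AR(1) altitude
#' jitter and pixel quantization are overlaid on the controlled path as output
#' noise (they model body oscillation and tracking error below the control
#' loop's bandwidth). The trajectory is returned at 100 Hz regardless of the
#' integration step.
#'
#' @param config A [sim_config()].
#' @param params A [controller_params()].
#' @param flight_id Identifier stored with the trajectory.
#' @return A `trajectory`: data.frame with columns `t`, `x`, `z` (10 ms
#'   spacing) and condition metadata in attributes.
#' @export
simulate_flight <- function(config, params = controller_params(),
                            flight_id = "flight") {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  geom <- config$geom; cfg <- config$rods
  dt <- config$dt
  dur <- min(config$duration, geom$length / config$forward_speed)
  n <- floor(round(dur / dt, 9)) + 1L
  half <- geom$width / 2
  run_time <- (half - 0.5) / cfg$rate
  dynamic <- grepl("^dynamic", cfg$mode)
  sgn <- if (cfg$mode == "dynamic_converging") 1 else -1
  os_access <- config$texture$os_access
  z <- numeric(n)
  z[1] <- config$entry_altitude
  vz <- 0
  lam <- params$actuator_rate
  zmin <- 1e-3; zmax <- geom$height - 1e-3
  for (i in seq_len(n - 1L)) {
    t <- (i - 1L) * dt
    stim <- if (dynamic && t >= cfg$onset && t < cfg$onset + run_time) {
      sgn * cfg$rate
    } else 0
    rel_os <- -vz / z[i]
    rel_sa <- rel_os + stim / half   # relative SARC: self-motion + stimulation
    cmd <- cmd_vz_core(rel_os, rel_sa, os_access, params, z[i])
    vz <- vz + lam * dt * (cmd - vz)
    z[i + 1L] <- min(max(z[i] + vz * dt, zmin), zmax)
  }
  # resample to the 100 Hz tracking rate
  m <- as.integer(round(0.01 / dt))
  keep <- seq(1L, n, by = m)
  t_out <- round((keep - 1L) * dt, 9)
  z_out <- z[keep]
  if (config$altitude_noise_sd > 0) {
    z_out <- z_out + ar1_noise(length(z_out), config$altitude_noise_sd,
                               exp(-0.01 / config$noise_corr_time))
  }
  if (config$pixel_quantize) {
    px <- 71 / 210
    z_out <- round(z_out / px) * px
  }
  z_out <- pmin(pmax(z_out, zmin), zmax)
  out <- data.frame(t = t_out, x = config$forward_speed * t_out, z = z_out)
  structure(out,
            class = c("trajectory", "data.frame"),
            flight_id = flight_id,
            mode = cfg$mode, texture = config$texture$kind,
            experiment = if (grepl("^dynamic", cfg$mode)) "exp1"
                         else if (grepl("^static", cfg$mode)) "exp2" else "control",
            forward_speed = config$forward_speed)
}

# stationary AR(1) series, marginal sd `sd`, lag-1 correlation `rho`
ar1_noise <- function(n, sd, rho) {
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
  }
  e
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d samples at 10 ms, mode %s, %s ground\n",
              attr(x, "flight_id"), nrow(x), attr(x, "mode"), attr(x, "texture")))
  cat(sprintf("  altitude %.2f -> %.2f cm (median %.2f)\n",
              x$z[1], x$z[nrow(x)], stats::median(x$z)))
  invisible(x)
}
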