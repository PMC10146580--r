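#' Default 16-cell condition grid
#'
#' Experiment 1 (dynamic rod motion) and experiment 2 (static rod position),
#' each with four rod modes crossed with the two ground textures.
#'
#' @return data.frame with columns `mode`, `texture`, `experiment`.
#' @export
default_conditions <- function() {
  exp1 <- c("parallel", "narrow", "dynamic_converging", "dynamic_diverging")
  exp2 <- c("parallel", "narrow", "static_converging", "static_diverging")
  rbind(
    expand.grid(mode = exp1, texture = c("white", "striped"),
                experiment = "exp1", stringsAsFactors = FALSE),
    expand.grid(mode = exp2, texture = c("white", "striped"),
                experiment = "exp2", stringsAsFactors = FALSE)
  )
}

#' Synthetic cohort specification
#'
#' Describes the statistical structure of a simulated experiment: which
#' condition cells to fly, how many flights per cell, the between-flight
#' forward-speed and entry-altitude distributions, the within-flight altitude
#' jitter, and the master seed. Defaults state the emulated world: 10 flights
#' per cell, forward speed 55 +/- 5 cm/s (truncated to \[35, 75\]), entry at
#' 14 +/- 0.5 cm, 0.25 cm stationary jitter, pixel quantization on.
#'
#' @param conditions data.frame with columns `mode`, `texture`, `experiment`.
#' @param n_flights Flights per condition cell (>= 2).
#' @param speed_mean,speed_sd,speed_range Forward-speed distribution (cm/s).
#' @param entry_mean,entry_sd Entry-altitude distribution (cm).
#' @param noise_sd Stationary sd of the within-flight altitude jitter (cm).
#' @param quantize Logical; quantize output altitudes to the vertical pixel
#'   size (71/210 cm).
#' @param rod_onset,rod_rate Rod motion onset (s) and speed (cm/s).
#' @param duration Maximum flight duration (s).
#' @param seed Master seed (integer).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(conditions = default_conditions(), n_flights = 10,
                        speed_mean = 55, speed_sd = 5, speed_range = c(35, 75),
                        entry_mean = 14, entry_sd = 0.5,
                        noise_sd = 0.25, quantize = TRUE,
                        rod_onset = 2, rod_rate = 2, duration = 4, seed = 1) {
  if (n_flights < 2) stop("n_flights must be at least 2")
  if (speed_sd < 0 || entry_sd < 0 || noise_sd < 0) stop("sds must be non-negative")
  stopifnot(all(c("mode", "texture", "experiment") %in% names(conditions)))
  structure(
    list(conditions = conditions, n_flights = n_flights,
         speed_mean = speed_mean, speed_sd = speed_sd, speed_range = speed_range,
         entry_mean = entry_mean, entry_sd = entry_sd, noise_sd = noise_sd,
         quantize = isTRUE(quantize), rod_onset = rod_onset, rod_rate = rod_rate,
         duration = duration, seed = as.integer(seed)),
    class = "cohort_spec")
}

# counter-based seed split: the child seed depends only on (master, condition
# index, flight index), so changing the cohort size never reshuffles the
# flights of other cells or earlier flights of the same cell
child_seed <- function(master, condition, flight) {
  counter <- as.double(condition) * 1e5 + as.double(flight)
  as.integer((as.double(master) * 48271 + counter * 16807) %% 2147483647) + 1L
}

#' Generate a synthetic flight cohort
#'
#' Per flight: a forward speed is drawn once (normal, truncated to
#' `speed_range`), the entry altitude is jittered, and the closed-loop
#' simulator produces the trajectory under the flight's condition, using a
#' per-flight child seed derived from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param params A [controller_params()].
#' @param geom A [tunnel_geometry()].
#' @return Named list of `trajectory` objects (names are flight ids
#'   `<mode>.<texture>.<experiment>.<i>`).
#' @export
generate_cohort <- function(spec, params = controller_params(),
                            geom = tunnel_geometry()) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  out <- list()
  for (ci in seq_len(nrow(spec$conditions))) {
    cond <- spec$conditions[ci, ]
    for (f in seq_len(spec$n_flights)) {
      set.seed(child_seed(spec$seed, ci, f))
      vx <- truncnorm1(spec$speed_mean, spec$speed_sd, spec$speed_range)
      z0 <- spec$entry_mean + stats::rnorm(1, 0, spec$entry_sd)
      z0 <- min(max(z0, 1), geom$height - 1)
      cfg <- sim_config(
        geom = geom,
        rods = rod_config(cond$mode, onset = spec$rod_onset, rate = spec$rod_rate),
        texture = texture_condition(cond$texture),
        duration = spec$duration, forward_speed = vx, entry_altitude = z0,
        altitude_noise_sd = spec$noise_sd, pixel_quantize = spec$quantize)
      id <- sprintf("%s.%s.%s.%02d", cond$mode, cond$texture, cond$experiment, f)
      traj <- simulate_flight(cfg, params, flight_id = id)
      attr(traj, "experiment") <- cond$experiment
      attr(traj, "seed") <- child_seed(spec$seed, ci, f)
      out[[id]] <- traj
    }
  }
  out
}

# one draw from a normal truncated to [lo, hi] by rejection
truncnorm1 <- function(mean, sd, range) {
  if (sd == 0) return(mean)
  for (i in 1:1000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  stats::runif(1, range[1], range[2])
}

#' Write flight records to a directory
#'
#' One CSV per flight (`<id>.csv`, header `t_s,x_cm,z_cm`, one row per 10 ms
#' sample, four decimal places) plus a JSON sidecar (`<id>.json`) carrying the
#' flight id, rod mode, texture, experiment, forward speed and seed.
#'
#' @param trajs List of `trajectory` objects (as from [generate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the CSV files written.
#' @export
write_flights <- function(trajs, dir) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tr in trajs) {
    id <- attr(tr, "flight_id")
    csv <- file.path(dir, paste0(id, ".csv"))
    con <- file(csv, "w")
    writeLines("t_s,x_cm,z_cm", con)
    writeLines(sprintf("%.4f,%.4f,%.4f", tr$t, tr$x, tr$z), con)
    close(con)
    meta <- list(flight_id = id, mode = attr(tr, "mode"),
                 texture = attr(tr, "texture"),
                 experiment = attr(tr, "experiment"),
                 forward_speed = attr(tr, "forward_speed"),
                 seed = attr(tr, "seed"))
    jsonlite::write_json(meta, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, null = "null", digits = NA)
    paths <- c(paths, csv)
  }
  invisible(paths)
}

#' Read flight records from a directory
#'
#' Reads every `*.csv` flight file (with its JSON sidecar when present) and
#' validates the dialect: exact header, numeric fields, time starting at 0 and
#' advancing in strict 10 ms steps. Malformed files raise an error naming the
#' offending line.
#'
#' @param dir Directory holding flight CSVs written by [write_flights()].
#' @return Named list of `trajectory` objects.
#' @export
read_flights <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no flight CSV files found in ", dir)
  out <- list()
  for (f in files) {
    lines <- readLines(f)
    if (length(lines) < 2) stop("empty flight file: ", f)
    if (lines[1] != "t_s,x_cm,z_cm") {
      stop("bad header in ", f, " (line 1): expected 't_s,x_cm,z_cm'")
    }
    parts <- strsplit(lines[-1], ",", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop("malformed row in ", f, " at line ", bad[1] + 1)
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
    if (anyNA(vals)) {
      stop("non-numeric field in ", f, " at line ",
           which(apply(is.na(vals), 1, any))[1] + 1)
    }
    t <- vals[, 1]
    if (abs(t[1]) > 1e-9) stop("time must start at 0 in ", f, " (line 2)")
    dt <- diff(t)
    badt <- which(abs(dt - 0.01) > 1e-6)
    if (length(badt)) {
      stop("non-monotone or irregular time step in ", f, " at line ", badt[1] + 2)
    }
    id <- sub("\\.csv$", "", basename(f))
    tr <- data.frame(t = t, x = vals[, 2], z = vals[, 3])
    meta_path <- file.path(dir, paste0(id, ".json"))
    meta <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path, simplifyVector = TRUE)
    } else list()
    out[[id]] <- structure(tr, class = c("trajectory", "data.frame"),
                           flight_id = meta$flight_id %||% id,
                           mode = meta$mode %||% NA_character_,
                           texture = meta$texture %||% NA_character_,
                           experiment = meta$experiment %||% NA_character_,
                           forward_speed = meta$forward_speed %||% NA_real_,
                           seed = meta$seed %||% NA_integer_)
  }
  out
}
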