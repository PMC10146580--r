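#' Cropped-frame specification of the tracking camera
#'
#' The tracking video is cropped to 620 x 210 pixels covering 160 cm
#' (horizontal) by 71 cm (vertical, the full tunnel height); row 0 is the
#' tunnel top.
#'
#' @param px_width,px_height Crop size in pixels.
#' @param cm_width,cm_height Field covered, in cm.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(px_width = 620, px_height = 210,
                       cm_width = 160, cm_height = 71) {
  structure(list(px_width = px_width, px_height = px_height,
                 cm_width = cm_width, cm_height = cm_height),
            class = "frame_spec")
}

#' Vertical extent of one pixel (cm)
#'
#' @param frame A [frame_spec()].
#' @return Pixel height in cm (0.338 cm, i.e. 3.4 mm, for the default crop).
#' @export
pixel_height_cm <- function(frame = frame_spec()) {
  frame$cm_height / frame$px_height
}

#' Horizontal field of view of the tracking camera
#'
#' Full angle subtended by a plane of width `width_cm` at distance
#' `distance_cm` from the lens. Defaults reproduce the recording geometry:
#' a 160 cm field at 165 cm from the tunnel midline, about 52 degrees.
#'
#' @param width_cm Width of the imaged plane (cm).
#' @param distance_cm Distance from the lens to the plane (cm).
#' @return Field of view in degrees.
#' @export
camera_fov_deg <- function(width_cm = 160, distance_cm = 165) {
  2 * atan(width_cm / 2 / distance_cm) * 180 / pi
}

#' Calibrate pixel coordinates to tunnel coordinates
#'
#' Linear map of the cropped frame: 620 px correspond to 160 cm horizontally
#' and 210 px to 71 cm vertically, with row 0 at the tunnel top.
#'
#' @param col,row Pixel coordinates (vectors of equal length), within the frame.
#' @param frame A [frame_spec()].
#' @return data.frame with columns `x`, `z` in cm.
#' @export
calibrate <- function(col, row, frame = frame_spec()) {
  if (any(col < 0 | col > frame$px_width) || any(row < 0 | row > frame$px_height)) {
    stop("pixel coordinates outside the cropped frame")
  }
  data.frame(
    x = col * frame$cm_width / frame$px_width,
    z = frame$cm_height - row * frame$cm_height / frame$px_height
  )
}

#' Median-bin the altitude series of a trajectory
#'
#' Consecutive non-overlapping groups of `bin_samples` samples (15 samples =
#' 150 ms at the 100 Hz tracking rate); the altitude of each bin is the median
#' of its samples. A trailing partial bin is discarded. Bins are aligned to the
#' flight's first sample; bin centers are reported at the midpoint of each
#' 150 ms interval.
#'
#' @param traj A `trajectory` (data.frame with `t` and `z`).
#' @param bin_samples Samples per bin.
#' @return An object of class `binned_altitude`: data.frame with `bin_center`
#'   (s) and `z` (cm), carrying the flight id.
#' @export
bin_median <- function(traj, bin_samples = 15) {
  n <- nrow(traj)
  if (n < bin_samples) stop("need at least ", bin_samples, " samples to bin")
  nb <- n %/% bin_samples
  idx <- rep(seq_len(nb), each = bin_samples)
  zb <- as.numeric(tapply(traj$z[seq_len(nb * bin_samples)], idx, stats::median))
  dt <- traj$t[2] - traj$t[1]
  width <- bin_samples * dt
  centers <- traj$t[1] + (seq_len(nb) - 0.5) * width
  structure(data.frame(bin_center = centers, z = zb),
            class = c("binned_altitude", "data.frame"),
            flight_id = attr(traj, "flight_id"),
            bin_width = width)
}

#' Ground-following filter
#'
#' Keeps trajectories that track the ground rather than the ceiling. The
#' default criterion (this package's choice; the experimental one was never
#' published): median altitude below `max_median` (half the tunnel height) and
#' no sample within `ceiling_margin` of the ceiling. A custom `criterion`
#' function `(traj) -> logical` replaces the default entirely.
#'
#' @param traj A `trajectory`.
#' @param geom A [tunnel_geometry()].
#' @param max_median Maximum allowed median altitude (cm).
#' @param ceiling_margin Minimum allowed distance to the ceiling (cm).
#' @param criterion Optional replacement predicate.
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
ground_following_filter <- function(traj, geom = tunnel_geometry(),
                                    max_median = geom$height / 2,
                                    ceiling_margin = 0.5,
                                    criterion = NULL) {
  if (!is.null(criterion)) return(isTRUE(criterion(traj)))
  stats::median(traj$z) < max_median &&
    all(traj$z < geom$height - ceiling_margin)
}

#' Epoch matrix of binned altitudes around the perturbation onset
#'
#' Builds the flights x time-bins matrix the rank statistics run on:
#' `n_before` bins whose centers precede `onset` and `n_after` bins following
#' it, nearest to the onset. Flights too short to cover the window are dropped
#' with a warning. With `grid = "table"` the columns are instead the bins
#' nearest to the 0.25 s grid from 1.25 to 3 s used in the published pairwise
#' table.
#'
#' @param binned A list of [bin_median()] results (or a single one).
#' @param onset Perturbation onset (s).
#' @param n_before,n_after Number of bins on each side of the onset.
#' @param grid `"onset"` (default) or `"table"`.
#' @return An object of class `epoch_matrix`: numeric matrix, one row per
#'   flight, columns named by bin center; attributes `onset`, `bin_centers`.
#' @export
epoch_split <- function(binned, onset = 2, n_before = 3, n_after = 3,
                        grid = c("onset", "table")) {
  grid <- match.arg(grid)
  if (inherits(binned, "binned_altitude")) binned <- list(binned)
  if (length(binned) < 2) stop("need at least 2 flights for an epoch matrix")
  centers_of <- function(b) b$bin_center
  target_centers <- function(b) {
    cc <- centers_of(b)
    if (grid == "table") {
      sel <- vapply(seq(1.25, 3, by = 0.25),
                    function(g) which.min(abs(cc - g)), 0L)
      if (anyDuplicated(sel)) sel <- unique(sel)
      cc[sel]
    } else {
      pre <- cc[cc < onset]
      post <- cc[cc > onset]
      if (length(pre) < n_before || length(post) < n_after) return(NULL)
      c(utils::tail(pre, n_before), utils::head(post, n_after))
    }
  }
  rows <- list(); labels <- character(0); centers <- NULL
  for (b in binned) {
    tc <- target_centers(b)
    ok <- !is.null(tc) &&
      (grid == "onset" || max(abs(utils::tail(b$bin_center, 1))) >= 3)
    if (!ok) {
      warning("dropping flight '", attr(b, "flight_id") %||% "?",
              "': too short for the epoch window")
      next
    }
    if (is.null(centers)) centers <- tc
    vals <- b$z[match(tc, b$bin_center)]
    if (anyNA(vals)) {
      warning("dropping flight '", attr(b, "flight_id") %||% "?",
              "': bin grid mismatch")
      next
    }
    rows[[length(rows) + 1L]] <- vals
    labels <- c(labels, attr(b, "flight_id") %||% sprintf("flight%d", length(rows)))
  }
  if (length(rows) < 2) stop("fewer than 2 flights cover the epoch window")
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, format(centers, trim = TRUE))
  structure(m, class = c("epoch_matrix", "matrix"),
            onset = onset, bin_centers = centers)
}

#' Export an epoch matrix as CSV
#'
#' Header row holds the bin centers (s); one row per flight.
#'
#' @param em An [epoch_split()] result.
#' @param path Output file.
#' @export
write_epoch_csv <- function(em, path) {
  utils::write.csv(as.data.frame(unclass(em)), path, row.names = TRUE)
  invisible(path)
}
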