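#' Build a synthetic trajectory from an angular-velocity profile
#'
#' Integrates a prescribed angular-velocity and speed profile into a planar
#' path with the same bookkeeping as the embodied simulation. Useful for
#' constructing analysis fixtures with known segmentation properties.
#'
#' @param omega Angular velocity per step, in rad/ms.
#' @param speed Speed per step (recycled if scalar).
#' @param dt Time step (s).
#' @return A trajectory tibble (`step`, `time`, `x`, `y`, `heading`, `omega`,
#'   `speed`) as produced by [simulate_agent()].
#' @examples
#' zig <- synthetic_trajectory(rep(c(0.01, -0.01), each = 200, times = 5))
#' segment_trajectory(zig)
#' @export
synthetic_trajectory <- function(omega, speed = 0.5, dt = LAL_DT) {
  n <- length(omega)
  speed <- rep_len(speed, n)
  heading <- .wrap_angle(cumsum(omega * dt * 1e3))  # omega rad/ms, dt*1e3 ms
  x <- cumsum(speed * dt * cos(heading))
  y <- cumsum(speed * dt * sin(heading))
  tibble(step = seq_len(n), time = seq_len(n) * dt, x = x, y = y,
         heading = heading, omega = omega, speed = speed)
}

#' Segment a trajectory at turning-direction transitions
#'
#' Steps whose absolute angular velocity is below `omega_threshold` are
#' treated as low-level noise and excluded; transitions are the steps where
#' the sign of the remaining angular velocity changes. The underlying path is
#' the polyline through the animat positions at the transition steps.
#'
#' @param traj A trajectory tibble (from [simulate_agent()] or
#'   [synthetic_trajectory()]).
#' @param omega_threshold Mask threshold in rad/ms (default 1e-3).
#' @return A `trajectory_segments` object: list with `transition_indices`
#'   (step indices where the turning direction first takes its new sign),
#'   `underlying_path` (tibble of transition positions) and `segments`
#'   (tibble with `start`, `end`, `actual_length`, `chord_length`).
#' @export
segment_trajectory <- function(traj, omega_threshold = LAL_OMEGA_THRESHOLD) {
  if (nrow(traj) == 0) abort("trajectory is empty")
  s <- sign(traj$omega)
  s[abs(traj$omega) < omega_threshold] <- 0
  nz <- which(s != 0)
  trans <- integer(0)
  if (length(nz) > 1) {
    sig <- s[nz]
    flips <- which(sig[-1] != sig[-length(sig)])
    trans <- nz[flips + 1]            # step where the new sign first appears
  }
  upath <- traj[trans, c("step", "x", "y")]
  segments <- tibble(start = integer(0), end = integer(0),
                     actual_length = numeric(0), chord_length = numeric(0))
  if (length(trans) >= 2) {
    step_len <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    cum <- c(0, cumsum(step_len))     # path length up to row i
    a <- trans[-length(trans)]
    b <- trans[-1]
    segments <- tibble(
      start = a, end = b,
      actual_length = cum[b] - cum[a],
      chord_length = sqrt((traj$x[b] - traj$x[a])^2 + (traj$y[b] - traj$y[a])^2))
  }
  structure(list(transition_indices = trans, underlying_path = upath,
                 segments = segments, omega_threshold = omega_threshold),
            class = "trajectory_segments")
}

#' @export
print.trajectory_segments <- function(x, ...) {
  cat(sprintf("<trajectory_segments> %d transitions, %d segments\n",
              length(x$transition_indices), nrow(x$segments)))
  invisible(x)
}

#' Sinuosity and stability metrics of a segmented trajectory
#'
#' Sinuosity measures: per-segment excess of the actual path length over the
#' chord of the underlying path, the number of transitions, and segment
#' lengths. Stability measures: the signed angles between consecutive
#' underlying segments, the angle between the first and last underlying
#' segments, and the trajectory angle (direction from origin to final
#' position, measured against the initial heading, which is 0 at the start).
#'
#' @param traj The trajectory tibble.
#' @param seg Optional precomputed [segment_trajectory()] result.
#' @param omega_threshold Passed to [segment_trajectory()] when `seg` is NULL.
#' @return A `trajectory_metrics` list with fields `n_transitions`,
#'   `segment_lengths`, `sinuosity_diffs`, `intersegment_angles`,
#'   `first_last_angle`, `trajectory_angle`, `path_length`,
#'   `net_displacement`, `cum_heading`, `final_speed`. With fewer than two
#'   transitions the intersegment statistics are empty and stability rests on
#'   the trajectory angle alone.
#' @export
trajectory_metrics <- function(traj, seg = NULL,
                               omega_threshold = LAL_OMEGA_THRESHOLD) {
  if (is.null(seg)) seg <- segment_trajectory(traj, omega_threshold)
  segs <- seg$segments
  dirs <- numeric(0)
  if (nrow(segs) > 0) {
    dirs <- atan2(traj$y[segs$end] - traj$y[segs$start],
                  traj$x[segs$end] - traj$x[segs$start])
  }
  inter <- if (length(dirs) >= 2) .wrap_angle(diff(dirs)) else numeric(0)
  first_last <- if (length(dirs) >= 2)
    .wrap_angle(dirs[length(dirs)] - dirs[1]) else NA_real_
  n <- nrow(traj)
  traj_angle <- if (traj$x[n] == 0 && traj$y[n] == 0) 0 else
    atan2(traj$y[n], traj$x[n])       # initial heading is 0 along +x
  # the path starts at the origin; the first row is the pose after step 1
  step_len <- sqrt(diff(c(0, traj$x))^2 + diff(c(0, traj$y))^2)
  dt_ms <- traj$time[1] * 1e3          # first step time = dt
  structure(list(
    n_transitions = length(seg$transition_indices),
    segment_lengths = segs$chord_length,
    sinuosity_diffs = segs$actual_length - segs$chord_length,
    intersegment_angles = inter,
    first_last_angle = first_last,
    trajectory_angle = traj_angle,
    path_length = sum(step_len),
    net_displacement = sqrt(traj$x[n]^2 + traj$y[n]^2),
    cum_heading = sum(traj$omega) * dt_ms,  # rad (omega rad/ms * step in ms)
    final_speed = traj$speed[n]),
    class = "trajectory_metrics")
}

#' @export
print.trajectory_metrics <- function(x, ...) {
  cat(sprintf("<trajectory_metrics> %d transitions, trajectory angle %.3f rad\n",
              x$n_transitions, x$trajectory_angle))
  invisible(x)
}

#' @export
tidy.trajectory_metrics <- function(x, ...) {
  tibble(n_transitions = x$n_transitions,
         median_segment_length = if (length(x$segment_lengths)) median(x$segment_lengths) else NA_real_,
         median_sinuosity_diff = if (length(x$sinuosity_diffs)) median(x$sinuosity_diffs) else NA_real_,
         median_intersegment_angle = if (length(x$intersegment_angles)) median(x$intersegment_angles) else NA_real_,
         first_last_angle = x$first_last_angle,
         trajectory_angle = x$trajectory_angle,
         path_length = x$path_length,
         net_displacement = x$net_displacement,
         cum_heading = x$cum_heading,
         final_speed = x$final_speed)
}

#' Plot a trajectory with its underlying path
#'
#' @param object A `trajectory_segments` result.
#' @param traj The trajectory tibble it was computed from.
#' @param ... Unused.
#' @return A ggplot overlaying the path (grey) and the underlying polyline
#'   through the turning transitions (blue).
#' @export
autoplot.trajectory_segments <- function(object, traj, ...) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "grey50", linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
  if (nrow(object$underlying_path) > 1)
    p <- p + ggplot2::geom_path(data = object$underlying_path,
                                colour = "steelblue") +
      ggplot2::geom_point(data = object$underlying_path, colour = "steelblue",
                          size = 0.8)
  p
}
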