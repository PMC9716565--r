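#' Actuator parameters
#'
#' Actuators are non-spiking leaky integrators: each incoming spike adds
#' `gain` to the stored velocity, which decays with time constant `tau_act`
#' and saturates at `v_max`. The saturation value reached under a prolonged
#' spike train is the maximum velocity. Defaults are chosen so a sustained
#' 60 Hz train saturates the integrator (`gain = v_max / (60 * tau_act)`).
#'
#' @param tau_act Integrator time constant (s).
#' @param v_max Saturation velocity (length units / s).
#' @param gain Velocity increment per spike.
#' @param axle Distance between the two force integrators (length units),
#'   used by the differential-drive kinematics.
#' @param turn_gain Scalar mapping the averaged signed lateral command of the
#'   Comprehensive architecture to angular velocity (rad/s per unit level).
#' @return An `actuator_params` list.
#' @export
actuator_params <- function(tau_act = 0.1, v_max = 1,
                            gain = v_max / (60 * tau_act),
                            axle = 0.1, turn_gain = 4) {
  if (any(c(tau_act, v_max, gain, axle, turn_gain) <= 0))
    abort("actuator parameters must be positive")
  structure(list(tau_act = tau_act, v_max = v_max, gain = gain,
                 axle = axle, turn_gain = turn_gain),
            class = "actuator_params")
}

#' One actuator integration step
#'
#' @param level Current velocity level, in `[0, v_max]`.
#' @param n_spikes Number of incoming spikes this step.
#' @param params An [actuator_params()].
#' @param dt Time step (s).
#' @return `level * (1 - dt/tau_act) + gain * n_spikes`, clipped to
#'   `[0, v_max]`.
#' @export
actuator_update <- function(level, n_spikes, params, dt = LAL_DT) {
  pmin(params$v_max, pmax(0, level * (1 - dt / params$tau_act) +
                               params$gain * n_spikes))
}

.wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi)
  ifelse(w <= 0, w + pi, w - pi)
}

#' Differential-drive kinematics step
#'
#' The two force integrators sit on either side of the body centre; a higher
#' right velocity rotates the body to the left (positive heading change) and
#' vice versa. Position advances by the mean velocity along the new heading.
#'
#' @param vL,vR Left and right actuator velocities (>= 0).
#' @param pose Named list or vector with `x`, `y`, `heading`.
#' @param axle Distance between actuators.
#' @param dt Time step (s).
#' @return Updated pose list with `x`, `y`, `heading` (wrapped to (-pi, pi])
#'   and the step's `omega` (rad/s) and `speed`.
#' @export
core_kinematics <- function(vL, vR, pose, axle = 0.1, dt = LAL_DT) {
  omega <- (vR - vL) / axle
  heading <- .wrap_angle(pose$heading + omega * dt)
  speed <- (vL + vR) / 2
  list(x = pose$x + speed * dt * cos(heading),
       y = pose$y + speed * dt * sin(heading),
       heading = heading, omega = omega, speed = speed)
}

#' Split velocity/turning kinematics step
#'
#' Forward speed is common to both sides; each side carries a signed lateral
#' turn value (leftward minus rightward integrator level). The two side
#' values are averaged and scaled by `turn_gain` to give the angular
#' velocity, so unequal inner/outer turn commands produce differential
#' turning radii as in Ackermann steering.
#'
#' @param v_forward Forward velocity (>= 0).
#' @param left_side,right_side Signed lateral turn values (+ = leftward).
#' @param pose Named list with `x`, `y`, `heading`.
#' @param turn_gain rad/s per unit averaged lateral level.
#' @param dt Time step (s).
#' @return Updated pose list as in [core_kinematics()].
#' @export
comprehensive_kinematics <- function(v_forward, left_side, right_side, pose,
                                     turn_gain = 4, dt = LAL_DT) {
  omega <- turn_gain * (left_side + right_side) / 2
  heading <- .wrap_angle(pose$heading + omega * dt)
  list(x = pose$x + v_forward * dt * cos(heading),
       y = pose$y + v_forward * dt * sin(heading),
       heading = heading, omega = omega, speed = v_forward)
}

#' Simulate an embodied agent
#'
#' Couples the network simulation step-by-step to the actuator integrators
#' and planar kinematics of the architecture named in the network's
#' `architecture` attribute. In the Core architecture each output neuron
#' drives the contralateral force integrator (Braitenberg layout). In the
#' Comprehensive architecture both V neurons feed one forward integrator,
#' while IL/CL spikes feed per-side leftward/rightward turn integrators
#' (left motor centre: leftward from `IL_L`, rightward from `CL_R`; right
#' motor centre: rightward from `IL_R`, leftward from `CL_L`).
#'
#' @param net A `snn_network` built by [core_network()] or
#'   [comprehensive_network()].
#' @param cfg A [sim_config()].
#' @param act An [actuator_params()].
#' @param record_traces Keep membrane/adaptation/synapse traces.
#' @return An `animat_sim` object: an `snn_sim` with an extra `trajectory`
#'   tibble (columns `step`, `time` s, `x`, `y`, `heading` rad, `omega`
#'   rad/ms, `speed`).
#' @examples
#' sim <- simulate_agent(core_network(core_showcase()),
#'                       sim_config(n_steps = 500, seed = 2,
#'                                  input_currents = input_currents(0.5, 0.5)))
#' tail(sim$trajectory)
#' @export
simulate_agent <- function(net, cfg, act = actuator_params(),
                           record_traces = TRUE) {
  stopifnot(inherits(net, "snn_network"), inherits(cfg, "sim_config"))
  .check_taus(net, cfg$dt)
  arch <- attr(net, "architecture")
  if (is.null(arch))
    abort("network has no architecture attribute; build it with core_network() or comprehensive_network()")
  variant <- match(arch, c("core", "comprehensive"))
  motor <- if (arch == "core") c("O_L", "O_R") else
    c("V_L", "V_R", "IL_L", "IL_R", "CL_L", "CL_R")
  midx <- match(motor, net$neurons$id) - 1L
  nm <- .neuron_matrix(net, cfg$input_currents)
  sm <- .synapse_matrix(net)
  set.seed(cfg$seed)
  V0 <- .initial_V(net, cfg)
  raw <- .sim_snn_cpp(nm, sm, V0, cfg$dt, cfg$n_steps, cfg$noise_scale,
                      variant,
                      c(act$tau_act, act$gain, act$v_max, act$axle, act$turn_gain),
                      as.integer(midx), record_traces)
  sim <- .wrap_sim(raw, net, cfg, extra_class = "animat_sim")
  tr <- raw$trajectory
  sim$trajectory <- tibble(
    step = seq_len(nrow(tr)), time = tr[, 1], x = tr[, 2], y = tr[, 3],
    heading = tr[, 4], omega = tr[, 5] / 1e3,  # rad/s -> rad/ms
    speed = tr[, 6])
  sim$actuators <- act
  sim
}

#' @export
print.animat_sim <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("<animat_sim> %d steps, final position (%.3f, %.3f), heading %.2f rad\n",
              x$cfg$n_steps, last$x, last$y, last$heading))
  invisible(x)
}

#' Plot the animat path in the plane
#'
#' @param object An `animat_sim` from [simulate_agent()].
#' @param ... Unused.
#' @return A ggplot with equal axes; the start point is marked in red.
#' @export
autoplot.animat_sim <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(data = object$trajectory[1, ], colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [length units]", y = "y [length units]")
}
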