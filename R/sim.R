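#' Simulation settings
#'
#' @param n_steps Number of forward-Euler steps.
#' @param dt Time step in seconds (default 1 ms).
#' @param noise_scale Amplitude of the multiplicative noise numerator; the
#'   per-step noise term is `eta = noise_scale * u / dt` with `u` uniform on
#'   `[0, 1)`, redrawn independently per neuron per step. Set 0 to disable.
#' @param seed Integer seed for the noise stream.
#' @param input_currents Named numeric vector of constant external currents
#'   (amperes) keyed by neuron id, typically built with [input_currents()].
#' @param init Initial membrane potentials: `"random"` (default) draws each
#'   neuron's starting potential uniformly between `V_reset` and `V_th` from
#'   the seeded stream, which seeds the left/right asymmetry that the
#'   half-centre dynamics amplify; `"rest"` starts every neuron at `V_leak`
#'   (bit-identical sides, useful as a symmetry control); or a numeric vector
#'   of potentials, one per neuron.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_steps = LAL_N_STEPS, dt = LAL_DT,
                       noise_scale = LAL_NOISE_SCALE, seed = 1L,
                       input_currents = NULL, init = "random") {
  if (dt <= 0 || n_steps < 1 || noise_scale < 0)
    abort("need dt > 0, n_steps >= 1, noise_scale >= 0")
  if (is.character(init) && !init %in% c("random", "rest"))
    abort("init must be 'random', 'rest' or a numeric vector")
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 noise_scale = noise_scale, seed = as.integer(seed),
                 input_currents = input_currents, init = init),
            class = "sim_config")
}

# Initial potentials; called after set.seed so "random" is reproducible.
.initial_V <- function(net, cfg) {
  n <- nrow(net$neurons)
  if (is.numeric(cfg$init)) {
    if (length(cfg$init) != n) abort("init vector must have one entry per neuron")
    return(cfg$init)
  }
  vl <- vapply(net$neurons$params, `[[`, numeric(1), "V_leak")
  if (identical(cfg$init, "rest")) return(vl)
  vr <- vapply(net$neurons$params, `[[`, numeric(1), "V_reset")
  vt <- vapply(net$neurons$params, `[[`, numeric(1), "V_th")
  vr + (vt - vr) * runif(n)
}

.check_taus <- function(net, dt) {
  taus <- vapply(net$neurons$params, `[[`, numeric(1), "tau_adapt")
  if (any(taus <= dt))
    abort("tau_adapt must exceed dt for a stable Euler decay")
  if (nrow(net$synapses) > 0 && any(net$synapses$tau_syn <= dt))
    abort("tau_syn must exceed dt for a stable Euler decay")
}

#' Simulate a spiking network
#'
#' Integrates the network with a forward-Euler scheme at constant `dt`.
#' Per step, in fixed order: synaptic currents from the previous step's
#' activations and voltages; membrane update for every neuron not in the
#' spike clamp or refractory hold; threshold detection with spike bookkeeping
#' (one-step `V_spike` clamp, reset, adaptation increment `delta_A`, +0.1 on
#' every outgoing synapse activation); Euler decay of adaptation and synapse
#' variables. The result is deterministic given `(net, cfg, seed)`.
#'
#' @param net A `snn_network` from [network_spec()] or a builder.
#' @param cfg A [sim_config()].
#' @param record_traces Keep per-step membrane, adaptation and synapse traces
#'   (matrices with `n_steps + 1` rows including the initial state). Spike
#'   times are always recorded.
#' @return An `snn_sim` object: list with `spikes` (named list of sorted spike
#'   times in seconds), trace matrices `V`, `A`, `S`, the `network` and `cfg`.
#' @examples
#' net <- core_network(core_showcase())
#' cfg <- sim_config(n_steps = 500, seed = 1,
#'                   input_currents = input_currents(0.5, 0.5))
#' sim <- simulate_network(net, cfg)
#' glance(sim)
#' @export
simulate_network <- function(net, cfg, record_traces = TRUE) {
  stopifnot(inherits(net, "snn_network"), inherits(cfg, "sim_config"))
  .check_taus(net, cfg$dt)
  nm <- .neuron_matrix(net, cfg$input_currents)
  sm <- .synapse_matrix(net)
  set.seed(cfg$seed)
  V0 <- .initial_V(net, cfg)
  raw <- .sim_snn_cpp(nm, sm, V0, cfg$dt, cfg$n_steps, cfg$noise_scale,
                      0L, numeric(5), integer(0), record_traces)
  .wrap_sim(raw, net, cfg)
}

.wrap_sim <- function(raw, net, cfg, extra_class = character()) {
  names(raw$spikes) <- net$neurons$id
  if (!is.null(raw$V)) colnames(raw$V) <- net$neurons$id
  if (!is.null(raw$A)) colnames(raw$A) <- net$neurons$id
  structure(list(spikes = raw$spikes, V = raw$V, A = raw$A, S = raw$S,
                 network = net, cfg = cfg,
                 times = seq(0, by = cfg$dt, length.out = cfg$n_steps + 1)),
            class = c(extra_class, "snn_sim"))
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf("<snn_sim> %d neurons, %d steps of %g ms, %d spikes\n",
              nrow(x$network$neurons), x$cfg$n_steps, x$cfg$dt * 1e3,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Tidy a simulation into a long tibble
#'
#' @param x An `snn_sim`.
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `time`, `V`, `A` (one row per
#'   neuron per recorded step). Requires traces to have been recorded.
#' @export
tidy.snn_sim <- function(x, ...) {
  if (is.null(x$V)) abort("simulation was run without trace recording")
  ids <- x$network$neurons$id
  purrr::map_dfr(seq_along(ids), function(i) {
    tibble(neuron = ids[i], time = x$times, V = x$V[, i], A = x$A[, i])
  })
}

#' One-row summary of a simulation
#'
#' @param x An `snn_sim`.
#' @param ... Unused.
#' @return A tibble with `n_neurons`, `n_steps`, `duration` (s), `n_spikes`
#'   and `mean_rate` (Hz per neuron).
#' @export
glance.snn_sim <- function(x, ...) {
  dur <- x$cfg$n_steps * x$cfg$dt
  tibble(n_neurons = nrow(x$network$neurons), n_steps = x$cfg$n_steps,
         duration = dur, n_spikes = sum(lengths(x$spikes)),
         mean_rate = sum(lengths(x$spikes)) / nrow(x$network$neurons) / dur)
}

#' Per-neuron firing rates
#'
#' @param sim An `snn_sim`.
#' @return A tibble with `neuron`, `n_spikes`, `rate` (Hz).
#' @export
firing_rates <- function(sim) {
  dur <- sim$cfg$n_steps * sim$cfg$dt
  tibble(neuron = names(sim$spikes), n_spikes = lengths(sim$spikes),
         rate = lengths(sim$spikes) / dur)
}

#' Plot membrane traces
#'
#' @param object An `snn_sim`.
#' @param neurons Optional character vector of neuron ids to show.
#' @param ... Unused.
#' @return A ggplot of membrane potential (mV) over time, one facet per neuron.
#' @export
autoplot.snn_sim <- function(object, neurons = NULL, ...) {
  d <- tidy(object)
  if (!is.null(neurons)) d <- filter(d, .data$neuron %in% neurons)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$V * 1e3)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~neuron) +
    ggplot2::labs(x = "time [s]", y = "membrane potential [mV]")
}

# ---- elementary update rules (exposed for direct use and testing) ----------

#' One membrane Euler step
#'
#' Applies the update
#' `V + (dt/Cm) * (g_leak*(V_leak - V) + g_adapt*A^p*(V_adapt - V) + I0 +
#' I_syn) * (1 + eta)` with `eta = noise_scale * noise_draw / dt`. The
#' adaptation term is dropped when `params$adapting` is `FALSE`.
#'
#' @param V Membrane potential (V); may be a vector.
#' @param params A [neuron_params()] list.
#' @param A Adaptation variable (same length as `V` or scalar).
#' @param I_syn Synaptic plus external current (A).
#' @param noise_draw Uniform draw on `[0, 1)` (0 for the noise-free update).
#' @param dt Time step (s).
#' @param noise_scale Noise amplitude (numerator of eta).
#' @return Updated membrane potential(s).
#' @export
membrane_step <- function(V, params, A = 0, I_syn = 0, noise_draw = 0,
                          dt = LAL_DT, noise_scale = LAL_NOISE_SCALE) {
  if (!all(is.finite(V), is.finite(A), is.finite(I_syn), is.finite(noise_draw)))
    abort("non-finite inputs to membrane_step")
  drive <- params$g_leak * (params$V_leak - V) + params$I0 + I_syn
  if (isTRUE(params$adapting))
    drive <- drive + params$g_adapt * A^params$p * (params$V_adapt - V)
  eta <- noise_scale * noise_draw / dt
  V + dt / params$Cm * drive * (1 + eta)
}

#' Euler decay of the adaptation variable
#'
#' @param A Adaptation value(s), non-negative.
#' @param tau_adapt Decay time constant (s); must exceed `dt`.
#' @param dt Time step (s).
#' @return `A * (1 - dt/tau_adapt)`, floored at 0.
#' @export
decay_adaptation <- function(A, tau_adapt, dt = LAL_DT) {
  if (tau_adapt <= dt) abort("tau_adapt must exceed dt")
  pmax(0, A * (1 - dt / tau_adapt))
}

#' Euler decay of a synapse activation
#'
#' @param S Activation value(s), non-negative.
#' @param tau_syn Decay time constant (s); must exceed `dt`.
#' @param dt Time step (s).
#' @return `S * (1 - dt/tau_syn)`.
#' @export
decay_synapse <- function(S, tau_syn, dt = LAL_DT) {
  if (tau_syn <= dt) abort("tau_syn must exceed dt")
  S * (1 - dt / tau_syn)
}

#' Conductance-based synaptic current
#'
#' `I_syn = g_syn * S * (V_rev - V_post)` with `g_syn = |weight| * g_unit`.
#'
#' @param S Synapse activation (non-negative).
#' @param weight Signed connection weight; its sign selects the reversal class.
#' @param V_post Postsynaptic membrane potential (V).
#' @param g_unit Conductance per unit `|weight|` (S).
#' @return Current in amperes (positive = depolarizing).
#' @export
synaptic_current <- function(S, weight, V_post, g_unit = LAL_G_UNIT) {
  V_rev <- ifelse(weight < 0, LAL_SYNAPSE_CLASS$V_rev_in, LAL_SYNAPSE_CLASS$V_rev_ex)
  abs(weight) * g_unit * S * (V_rev - V_post)
}

#' Spike density function
#'
#' Firing-rate estimate obtained by convolving a spike train with a
#' zero-mean Gaussian kernel (default sigma 50 ms) truncated to a finite
#' window (default 500 ms total width) and renormalized to unit integral, so
#' that the time integral of the SDF equals the spike count up to edge
#' truncation.
#'
#' @param spikes Numeric vector of spike times (s); may be empty.
#' @param n_steps,dt Length and resolution of the output series.
#' @param sigma Kernel standard deviation (s).
#' @param window Total width of the truncated kernel support (s).
#' @return A tibble with columns `time` (s) and `rate` (Hz) of length `n_steps`.
#' @export
spike_density_function <- function(spikes, n_steps, dt = LAL_DT,
                                   sigma = LAL_SDF_SIGMA, window = LAL_SDF_WINDOW) {
  if (sigma <= 0) abort("sigma must be positive")
  times <- seq_len(n_steps) * dt
  rate <- .sdf_values(spikes, n_steps, dt, sigma, window)
  tibble(time = times, rate = rate)
}

# Internal numeric SDF (used in the sweep hot path without tibble overhead).
.sdf_values <- function(spikes, n_steps, dt, sigma = LAL_SDF_SIGMA,
                        window = LAL_SDF_WINDOW) {
  if (length(spikes) == 0) return(numeric(n_steps))
  half <- floor(window / 2 / dt)
  kern <- dnorm(seq(-half, half) * dt, mean = 0, sd = sigma)
  kern <- kern / (sum(kern) * dt)   # unit integral after truncation
  counts <- tabulate(pmin(pmax(round(spikes / dt), 1), n_steps), nbins = n_steps)
  full <- stats::convolve(counts, rev(kern), type = "open")  # length n + 2*half
  full[(half + 1):(half + n_steps)]
}
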