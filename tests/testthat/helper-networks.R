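# Shared fixtures: small networks and closed-form oracles used across files.

# A single neuron with the tonic output-neuron drive, no synapses.
isolated_o_neuron <- function(I0 = 3.7698e-10) {
  neurons <- tibble::tibble(id = "O", label = "O", side = "L",
                            params = list(neuron_params(I0 = I0)))
  network_spec(neurons, data.frame(pre = character(), post = character(),
                                   weight = numeric()))
}

# Geometric-recurrence oracle for the noise-free LIF under Euler integration:
# number of update steps needed to rise from V_start to V_th.
lif_steps_to_threshold <- function(p, I0 = p$I0, V_start = p$V_reset) {
  V_inf <- p$V_leak + I0 / p$g_leak
  a <- LAL_DT * p$g_leak / p$Cm
  ceiling(log((p$V_th - V_inf) / (V_start - V_inf)) / log(1 - a))
}

# Closed-form discrete recurrence for the subthreshold membrane trace.
lif_recurrence <- function(p, I0, n_steps, V0) {
  a <- LAL_DT * p$g_leak / p$Cm
  b <- LAL_DT / p$Cm * (p$g_leak * p$V_leak + I0)
  V <- numeric(n_steps + 1)
  V[1] <- V0
  for (k in seq_len(n_steps)) V[k + 1] <- V[k] * (1 - a) + b
  V
}

# Battery of four symmetric-input trajectory metrics from omega profiles
# (rad/ms), for condition/classification tests.
metrics_from_omegas <- function(omega_list, speed = 0.5) {
  lapply(omega_list, function(om)
    trajectory_metrics(synthetic_trajectory(om, speed = speed)))
}

# Square-wave omega profile: amplitude amp, half-period half (steps).
# centered = TRUE starts with a half-length block so the heading oscillates
# symmetrically about zero and the path progresses along the initial heading.
square_omega <- function(n, half, amp = 0.01, centered = FALSE) {
  off <- if (centered) half %/% 2 else 0
  amp * rep_len(rep(c(1, -1), each = half), n + off)[(off + 1):(n + off)]
}
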