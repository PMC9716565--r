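test_that("membrane update has the leak fixed point and honours constructed balance", {
  p <- neuron_params()
  expect_equal(membrane_step(p$V_leak, p, noise_scale = 0), p$V_leak)
  # I_syn chosen to cancel the leak exactly: any V is stationary
  for (V in c(-0.07, -0.055, -0.052)) {
    I_bal <- -p$g_leak * (p$V_leak - V) - p$I0
    expect_equal(membrane_step(V, p, I_syn = I_bal, noise_scale = 0), V)
  }
  expect_error(membrane_step(NaN, p), "non-finite")
})

test_that("noise-free Euler trace equals the closed-form recurrence", {
  net <- isolated_o_neuron(I0 = 1e-11)  # subthreshold drive: no spikes
  cfg <- sim_config(n_steps = 2000, noise_scale = 0, seed = 1, init = "rest")
  sim <- simulate_network(net, cfg)
  p <- net$neurons$params[[1]]
  expect_length(sim$spikes$O, 0)
  oracle <- lif_recurrence(p, 1e-11, 2000, p$V_leak)
  expect_lt(max(abs(sim$V[, 1] - oracle) / abs(oracle)), 1e-12)
})

test_that("tonically driven neuron fires with the ISI the geometric recurrence predicts", {
  net <- isolated_o_neuron()
  p <- net$neurons$params[[1]]
  cfg <- sim_config(n_steps = 2000, noise_scale = 0, seed = 1, init = "rest")
  sim <- simulate_network(net, cfg)
  n_star <- lif_steps_to_threshold(p)
  expect_equal(n_star, 21)
  isi_ms <- diff(sim$spikes$O) * 1e3
  expect_equal(isi_ms, rep(n_star + 2, length(isi_ms)))
  # iterating membrane_step from V_reset crosses threshold at exactly n_star
  V <- p$V_reset; k <- 0
  while (V < p$V_th) { V <- membrane_step(V, p, noise_scale = 0); k <- k + 1 }
  expect_equal(k, n_star)
})

test_that("spike bookkeeping: clamp, reset, refractory floor on ISIs, A and S increments", {
  # strong drive: fires as fast as the refractory scheme allows
  net <- isolated_o_neuron(I0 = 5e-9)
  cfg <- sim_config(n_steps = 500, noise_scale = 0, seed = 1, init = "rest")
  sim <- simulate_network(net, cfg)
  p <- net$neurons$params[[1]]
  isi <- diff(sim$spikes$O)
  expect_true(all(isi >= p$t_refract + 2 * LAL_DT - 1e-12))
  # V_spike appears for one step, then V_reset
  s1 <- round(sim$spikes$O[1] / LAL_DT)
  expect_equal(unname(sim$V[s1 + 1, 1]), p$V_spike)
  expect_equal(unname(sim$V[s1 + 2, 1]), p$V_reset)

  # adaptation increment and synapse increment on one spike
  g <- core_genotype(w_EI = 1, w_EO = 1, w_II = -1, w_IO = -1,
                     g_adapt = 1e-7, delta_A = 0.1, p = 1, tau_adapt = 0.5)
  net2 <- core_network(g)
  cfg2 <- sim_config(n_steps = 300, noise_scale = 0, seed = 1, init = "rest",
                     input_currents = input_currents(1, 1))
  sim2 <- simulate_agent(net2, cfg2)
  iL <- which(net2$neurons$id == "I_L")
  s <- round(sim2$spikes$I_L[1] / LAL_DT)
  A_before <- sim2$A[s, iL]
  A_after <- sim2$A[s + 1, iL]
  # increment by delta_A then one decay step
  expect_equal(A_after, (A_before + 0.1) * (1 - LAL_DT / 0.5))
  # outgoing synapse jumped by 0.1 (then decayed once)
  j <- which(net2$synapses$pre == "I_L" & net2$synapses$post == "I_R")
  expect_equal(sim2$S[s + 1, j],
               (sim2$S[s, j] + 0.1) * (1 - LAL_DT / net2$synapses$tau_syn[j]))
})

test_that("adaptation and synapse decays match closed-form powers", {
  expect_equal(decay_adaptation(0, 0.05), 0)
  A <- 1
  for (i in 1:50) A <- decay_adaptation(A, 0.05)
  expect_equal(A, (1 - 0.02)^50)
  expect_equal(decay_adaptation(1, 0.5), 0.998)
  S <- 0.1
  for (i in 1:20) S <- decay_synapse(S, 0.02)
  expect_equal(S, 0.1 * 0.95^20)
  expect_equal(decay_synapse(0.1, 0.03), 0.1 * 29 / 30)
  expect_equal(decay_synapse(0, 0.02), 0)
  expect_error(decay_adaptation(1, 1e-3), "exceed")
  expect_error(decay_synapse(1, 5e-4), "exceed")
})

test_that("synaptic current follows the conductance equation and reversal classes", {
  expect_equal(synaptic_current(0, 2, -0.06), 0)
  # inhibitory synapse at its reversal potential passes no current
  expect_equal(synaptic_current(0.3, -2, -0.08), 0)
  # excitatory current is depolarizing below 0 mV
  expect_gt(synaptic_current(0.2, 1, -0.06), 0)
  # magnitude: |w| * g_unit * S * (V_rev - V)
  expect_equal(synaptic_current(0.2, -3, -0.06),
               3 * LAL_G_UNIT * 0.2 * (-0.08 + 0.06))
})

test_that("simulation is deterministic given the seed and respects invariants", {
  net <- core_network(core_showcase())
  cfg <- sim_config(n_steps = 400, seed = 42,
                    input_currents = input_currents(0.5, 0.5))
  a <- simulate_network(net, cfg)
  b <- simulate_network(net, cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$V, b$V)
  expect_true(all(a$A >= 0))
  expect_true(all(a$S >= 0))
  # A strictly decreasing between spikes of an adapting neuron
  iL <- which(net$neurons$id == "I_L")
  sp <- round(a$spikes$I_L / LAL_DT)
  if (length(sp) >= 2) {
    seg <- a$A[(sp[1] + 2):(sp[2]), iL]
    expect_true(all(diff(seg) < 0))
  }
  # different seed differs (noise + random init)
  d <- simulate_network(net, sim_config(n_steps = 400, seed = 43,
                                        input_currents = input_currents(0.5, 0.5)))
  expect_false(identical(a$V, d$V))
})

test_that("a symmetric network with identical initial state stays mirror-symmetric", {
  net <- core_network(core_showcase())
  cfg <- sim_config(n_steps = 1000, seed = 1, noise_scale = 0, init = "rest",
                    input_currents = input_currents(0.6, 0.6))
  sim <- simulate_network(net, cfg)
  expect_identical(sim$spikes$I_L, sim$spikes$I_R)
  expect_identical(sim$V[, "O_L"], sim$V[, "O_R"])
  # swapping the input sides mirrors the traces exactly
  cfg2 <- sim_config(n_steps = 1000, seed = 1, noise_scale = 0, init = "rest",
                     input_currents = input_currents(0.2, 0.9))
  cfg3 <- sim_config(n_steps = 1000, seed = 1, noise_scale = 0, init = "rest",
                     input_currents = input_currents(0.9, 0.2))
  s2 <- simulate_network(net, cfg2)
  s3 <- simulate_network(net, cfg3)
  expect_identical(s2$V[, "O_L"], s3$V[, "O_R"])
  expect_identical(s2$spikes$I_R, s3$spikes$I_L)
})

test_that("neurons without drive stay silent", {
  g <- core_genotype(w_EI = 1, w_EO = 1, w_II = -1, w_IO = -1,
                     g_adapt = 1e-7, delta_A = 0.1, p = 1, tau_adapt = 0.5)
  net <- core_network(g)
  cfg <- sim_config(n_steps = 2000, noise_scale = 0, seed = 1, init = "rest")
  sim <- simulate_network(net, cfg, record_traces = FALSE)
  expect_length(sim$spikes$E_L, 0)  # no input current
  expect_length(sim$spikes$I_L, 0)  # no presynaptic drive
})

test_that("spike density function integrates to the spike count and reads rates", {
  # empty train
  expect_true(all(spike_density_function(numeric(0), 1000)$rate == 0))
  # single interior spike: unimodal, peaks at the spike time, unit integral
  sdf <- spike_density_function(1.0, 2000)
  expect_equal(sdf$time[which.max(sdf$rate)], 1.0)
  expect_equal(sum(sdf$rate) * LAL_DT, 1, tolerance = 1e-6)
  expect_true(all(diff(sdf$rate[sdf$time < 1]) >= -1e-9))
  # regular 50 Hz train: interior plateau at 50 Hz
  train <- seq(0.02, 1.98, by = 0.02)
  sdf2 <- spike_density_function(train, 2000)
  interior <- sdf2$rate[sdf2$time > 0.5 & sdf2$time < 1.5]
  expect_equal(mean(interior), 50, tolerance = 0.01)
  expect_lt(max(abs(interior - 50)) / 50, 0.05)
  # integral equals count up to edge truncation
  expect_equal(sum(sdf2$rate) * LAL_DT, length(train), tolerance = 0.02)
  expect_error(spike_density_function(1, 100, sigma = 0), "sigma")
})
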