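# Model constants shared across the package. All quantities are SI unless the
# roxygen docs of the consuming function say otherwise.

# Membrane and spike constants common to every neuron in both architectures.
LAL_NEURON_DEFAULTS <- list(
  Cm        = 0.5e-9,   # membrane capacitance [F]
  g_leak    = 5e-9,     # leak conductance [S]
  V_leak    = -60e-3,   # leak reversal potential [V]
  V_th      = -50e-3,   # spike threshold [V]
  V_spike   = 20e-3,    # one-step spike clamp value [V]
  V_reset   = -65e-3,   # post-spike reset potential [V]
  V_adapt   = -70e-3,   # adaptation reversal potential [V]
  t_refract = 1e-3,     # refractory period [s]
  I0        = 0,        # tonic current offset [A]
  g_adapt   = 0,        # adaptation conductance [S]
  delta_A   = 0,        # adaptation increment per spike
  p         = 1,        # adaptation activation exponent
  tau_adapt = 0.1,      # adaptation decay time constant [s]
  adapting  = FALSE     # whether the adaptation current acts on this neuron
)

# Synapse class constants. The sign of a connection weight selects the class
# (excitatory vs inhibitory reversal and decay); |weight| scales conductance.
LAL_SYNAPSE_CLASS <- list(
  V_rev_ex   = 0,       # excitatory reversal potential [V]
  V_rev_in   = -80e-3,  # inhibitory reversal potential [V]
  tau_syn_ex = 20e-3,   # excitatory decay time constant [s]
  tau_syn_in = 30e-3,   # inhibitory decay time constant [s]
  s_increment = 0.1     # activation increment per presynaptic spike
)

# Conductance per unit |weight| [S]. The architecture tables print weights as
# dimensionless numbers; this constant maps them onto conductance such that a
# single presynaptic spike (S = 0.1) at unit weight produces a peak synaptic
# conductance of half the leak conductance (0.1 * 2.5e-8 = 2.5e-9 S). This is
# the scale at which the printed Core showcase genotype lies inside its
# intended operating regime: its CPG neurons are recruited even at 25% input
# (so the circuit can flip-flop there) while its output neurons stay under
# the 60 spikes/s exclusion cap at 100% input. An order of magnitude lower,
# no synapse can drive a postsynaptic spike at the printed weights; an order
# higher, the showcase itself would be excluded by the output-rate rule.
LAL_G_UNIT <- 2.5e-8

# Maximum static input current delivered to an input (E) neuron at 100%
# stimulus reliability [A].
LAL_I_MAX <- 1.75e-9

# Tonic current offsets [A] per population.
LAL_CORE_TONIC <- c(E = 0, I = 0, O = 3.7698e-10)
LAL_COMPREHENSIVE_TONIC <- c(E = 0, V = 1.22510e-10, IL = 5.5125e-11,
                             CL = 1.05e-10, A = 0, I = 0)

# Parameter grid columns for the Core architecture sweep (weights are shared
# across the four connections; inhibitory ones take the negative sign).
LAL_CORE_GRID <- list(
  w       = c(0.5, 1, 2, 3, 4),
  g_adapt = c(0.25, 0.5, 1, 2, 4) * 1e-7,
  delta_A = c(0.01, 0.05, 0.1, 0.2, 0.5),
  p       = c(1, 1.5, 2, 3, 4),
  tau_adapt = c(0.05, 0.1, 0.2, 0.3, 0.5)
)

# Phase-1 grid columns for the Comprehensive architecture sweep.
LAL_COMPREHENSIVE_GRID <- list(
  w_AI    = -(7:12),
  g_adapt = c(0.25, 0.5, 1, 2, 4) * 1e-7,
  p       = c(0.01, 0.05, 0.1, 0.2, 0.5),
  delta_A = 1:5,
  tau_adapt = c(0.05, 0.1, 0.2, 0.3, 0.5)
)

# Phase-2 inhibitory weight values explored for (w_IIL, w_ICL).
LAL_PHASE2_WEIGHTS <- c(-1, -2.6, -4.1, -5.7, -7.2, -8.8, -10.3, -11.9, -13.4, -15)

# Non-swept Comprehensive connection weights (documented defaults; the sweep
# explores only w_AI, w_IIL, w_ICL).
LAL_COMPREHENSIVE_FIXED <- list(
  w_EV = 1, w_EIL = 1, w_ECL = 1,  # input fan-out, excitatory
  w_VA = 1,                        # velocity -> adaptation, excitatory
  w_IV = -5,                       # inhibition of contralateral velocity
  w_CLIL = -2                      # Ackermann-like cross coupling
)

# Analysis thresholds.
LAL_OMEGA_THRESHOLD <- 1e-3   # low-turn mask [rad/ms]
LAL_ANGLE_LIMITS <- c(intersegment = 0.1, first_last = 0.25, trajectory = 0.25) # [rad]
LAL_RATE_LIMITS <- c(core = 60, comprehensive = 120)  # peak output rate [Hz]

# Default simulation settings.
LAL_DT <- 1e-3            # Euler time step [s]
LAL_N_STEPS <- 2000       # default run length [steps]
LAL_NOISE_SCALE <- 3e-6   # multiplicative noise amplitude (eta numerator)

# Spike density function defaults.
LAL_SDF_SIGMA <- 0.05     # Gaussian kernel width [s]
LAL_SDF_WINDOW <- 0.5     # kernel truncation window [s]
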