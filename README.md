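# lalcpg

Spiking-network central pattern generators inspired by the insect lateral
accessory lobe (LAL), with an embodied animat and trajectory analysis.

The LAL is a conserved pre-motor area of the insect brain that turns
navigation signals into steering commands. When the guiding stimulus is
reliable, the LAL passes a lateralized steering signal through; when it is
unreliable, the LAL generates an intrinsic rhythm that alternately activates
the left and right descending pathways ("flip-flop"), producing the
zig-zagging search movements seen in silkmoths, ants and other insects. This
package is for computational neuroscientists and roboticists who want to
simulate that mechanism, explore its parameter space, and quantify the
movement patterns it produces.

## The model

Neurons are leaky integrate-and-fire units with spike-rate adaptation,

dV/dt = (1/Cm) [ g_leak (V_leak − V) + g_adapt A^p (V_adapt − V) + I0 + I_syn ] (1 + η),

integrated by forward Euler at Δt = 1 ms. A spike at V ≥ V_th clamps V to
V_spike for one step, then to V_reset for the refractory period; each spike
increments the adaptation variable (A ← A + ΔA) and every outgoing synapse
activation (S ← S + 0.1). A and S decay exponentially (τ_adapt; 20 ms
excitatory / 30 ms inhibitory). Synaptic currents are conductance-based,
I_syn = g_syn S (V_rev − V), with reversal 0 mV (excitatory) or −80 mV
(inhibitory) chosen by the sign of the connection weight. η is a
multiplicative noise term redrawn per neuron per step.

Two architectures are provided:

* **Core** — 6 neurons. Inputs (E) excite the ipsilateral CPG neuron (I) and
  output neuron (O); each adapting I neuron inhibits the contralateral I and
  O. The O neurons drive the contralateral force integrators of a
  differential-drive animat (Braitenberg layout). Mutual inhibition plus
  adaptation makes the two sides alternate — a half-centre oscillator.
* **Comprehensive** — 12 neurons with split motor control: velocity neurons
  (V) set the forward speed of both actuator sides, ipsi- and contralaterally
  descending turning neurons (IL, CL) carry the left/right turn commands, and
  a V→A→I loop closes the CPG through contralateral inhibition. The CL→IL
  cross-coupling differentiates inner and outer turn commands, emulating
  Ackermann steering.

Trajectories are segmented at the points where the angular velocity changes
sign (turns below 10⁻³ rad/ms are treated as noise); the polyline through
those points is the underlying path. Sinuosity (arc-minus-chord length per
segment, segment counts and lengths) and stability (intersegment angles,
first-to-last segment angle, trajectory angle) feed six selection conditions
and a six-way movement-phenotype classification (zig-zag, straight, curve,
loop, chaos, stopping, with seven zig-zag subtypes).

## Worked example

Simulate the embodied Core network under 50 % symmetric input (an unreliable
stimulus) and quantify its search pattern:

```r
library(lalcpg)

net <- core_network(core_showcase())   # w_EI = 0.5, w_EO = 0.5, w_II = -3, w_IO = -5
cfg <- sim_config(n_steps = 2000, seed = 1,
                  input_currents = input_currents(0.5, 0.5))
sim <- simulate_agent(net, cfg)
sim
#> <animat_sim> 2000 steps, final position (1.619, -0.241), heading -0.16 rad

firing_rates(sim)
#> # A tibble: 6 × 3
#>   neuron n_spikes  rate
#>   <chr>     <int> <dbl>
#> 1 E_L         182  91
#> 2 E_R         182  91
#> 3 I_L          10   5
#> 4 I_R          10   5
#> 5 O_L         103  51.5
#> 6 O_R         104  52
```

The input neurons fire identically at 91 Hz, yet the CPG neurons (I) and the
outputs (O) alternate in anti-phase, so the agent zig-zags:

```r
segment_trajectory(sim$trajectory)
#> <trajectory_segments> 15 transitions, 14 segments

tidy(trajectory_metrics(sim$trajectory))
#> # A tibble: 1 × 10
#>   n_transitions median_segment_length median_sinuosity_diff ...
#> 1            15                0.0999            0.00000989
```

Fifteen turning-direction transitions in a 2-s run, short straight-ish
segments, and a trajectory angle of −0.15 rad: a tight zig-zag that still
progresses along the initial heading. `autoplot(sim)` draws the path;
raising the symmetric input level makes the switching faster and the path
straighter, while asymmetric input (`input_currents(0.25, 1)`) produces a
deterministic turn toward the stronger side.

Larger experiments follow the same grammar: `sweep_genotypes()` runs the
five-condition input battery over a genotype grid (`core_grid()`,
`comprehensive_phase1_grid()`), applies the exclusion rules, scores the six
sinuosity/stability conditions and classifies phenotypes;
`noise_robustness()` repeats the symmetric conditions under scaled noise
amplitudes. A thin command-line front end with the same operations ships in
`inst/cli/lalcpg`.

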