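---
title: "An adapting spiking half-centre model of insect pre-motor steering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adapting spiking half-centre model of insect pre-motor steering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lalcpg)
```

## The model and its assumptions

The insect lateral accessory lobe (LAL) converts navigation signals into
steering commands and, when those signals are unreliable, generates an
intrinsic left/right alternation that drives zig-zagging search. `lalcpg`
models this with networks of adapting leaky integrate-and-fire neurons:

$$\frac{dV}{dt} = \frac{1}{C_m}\Big(g_{leak}(V_{leak}-V) +
g_{adapt}A^{p}(V_{adapt}-V) + I_0 + I_{syn}\Big)(1+\eta)$$

integrated by forward Euler at $\Delta t = 1$ ms. When $V$ crosses
$V_{th} = -50$ mV the membrane is clamped to $V_{spike} = 20$ mV for one
step, assigned $V_{reset} = -65$ mV on the next, and held there for the
refractory period $t_{refract} = 1$ ms, so consecutive spikes are at least
$t_{refract} + 2\Delta t$ apart. Each spike increments the adaptation
variable ($A \leftarrow A + \Delta A$) and the activation $S$ of every
outgoing synapse by 0.1; both decay exponentially
($\tau_{adapt}$; $\tau_{syn} = 20$ ms excitatory, $30$ ms inhibitory).
Synaptic currents are conductance-based, $I_{syn} = g_{syn} S (V_{rev}-V)$
with $V_{rev} = 0$ mV (excitatory) or $-80$ mV (inhibitory). The sign of a
connection weight selects the synapse class only; $|w|$ scales the
conductance. $\eta = 3\times10^{-6}\,u/\Delta t$ ($u$ uniform on $[0,1)$,
redrawn per neuron per step) is a small multiplicative noise.

Within a step the update order is fixed: synaptic currents from the previous
step's $S$ and $V$; membrane update for all unclamped neurons; threshold
detection and spike bookkeeping; decay of $A$ and $S$; actuator and
kinematics update. This synchronous convention makes every simulation
bit-reproducible given `(network, config, seed)`.

The **Core** architecture (6 neurons) realizes the mechanism minimally:
input neurons E excite the ipsilateral CPG neuron I and output neuron O;
each adapting I inhibits the contralateral I and O. Mutual inhibition plus
spike-rate adaptation forms a half-centre oscillator: the dominant side
suppresses the other until its own adaptation releases it. The
**Comprehensive** architecture (12 neurons) separates motor roles: velocity
neurons V (forward speed, both sides), ipsi/contralaterally descending
turning neurons IL and CL, and a V→A→I loop that closes the CPG through
contralateral inhibition; CL→IL cross-coupling weakens the outer turn
command relative to the inner one (Ackermann-like steering). In the
Comprehensive phase-1 grid the A→I weight is printed negative; under the
sign convention this makes the A→I synapse inhibitory, in which case the I
neurons — which have no other input and no tonic drive — cannot fire and the
CPG loop stays open. We implement the printed sign faithfully and expose the
class through the weight's sign, noting that an excitatory A→I reading
(e.g. `comprehensive_genotype(w_AI = 2.5, ...)`) is required for the
oscillation to engage.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `Cm`, `g_leak`, `V_leak` | 0.5 nF, 5 nS, −60 mV | | passive membrane; time constant 100 ms |
| `I0` (Core O) | 3.7698e-10 | A | tonic drive; gives a 43.5 Hz spontaneous rate under this integrator (see below) |
| `g_adapt, ΔA, p, τ_adapt` | per genotype | S, –, –, s | adaptation strength and build-up/decay speed; the oscillation period grows with τ_adapt and shrinks with drive |
| `g_unit` | 2.5e-8 | S | conductance per unit \|weight\| (calibrated, below) |
| `I_max` | 1.75e-9 | A | input current at 100 % stimulus reliability |
| `tau_act`, `gain`, `v_max` | 0.1 s, 1/6, 1 | s, u, u/s | non-spiking actuator integrators; a sustained 60 Hz train saturates |
| `axle` | 0.1 | u | distance between force integrators; sets the angular-velocity scale |
| `omega_threshold` | 1e-3 | rad/ms | low-turn mask of the segmentation |

Three constants have no tabulated values and were fixed once, by the
following reasoning:

* **`g_unit` = 2.5e-8 S.** The weight tables are dimensionless. At this
  scale one presynaptic spike at unit weight contributes half a leak
  conductance, and the printed showcase genotype sits inside its intended
  operating regime: its CPG neurons are recruited even at 25 % input (so
  flip-flop is possible there) while its output neurons stay below the
  60 spikes/s exclusion cap under symmetric input. An order of magnitude
  lower no synapse can fire a postsynaptic neuron at the printed weights; an
  order higher the showcase itself trips the output-rate rule.
* **Actuator constants.** `tau_act` and `axle` were chosen so that the time
  scales separate around the segmentation mask: the per-spike ripple in the
  actuator difference stays below 1e-3 rad/ms while sustained one-sided
  dominance (the flip-flop signal, ~2.5–10e-3 rad/ms) rises well above it.
  Without that separation the mask either counts per-spike jitter as turns
  or swallows the flip-flop signal entirely.
* **Initial membrane potentials** are drawn uniformly between $V_{reset}$
  and $V_{th}$ from the seeded stream (`init = "random"`). The discrete
  noise-free dynamics are mode-locked — every neuron lands at a fixed
  sub-threshold phase of its cycle, and the µV-scale jitter of the printed
  noise amplitude can never split a threshold-crossing step — so from a
  bit-identical start the two sides stay symmetric indefinitely and no
  flip-flop can begin. Random initial potentials seed the asymmetry that the
  half-centre amplifies; the multiplicative noise then shapes the build-up
  phase and the run-to-run variability. `init = "rest"` provides the
  identical-state control, under which a noise-free symmetric simulation
  provably never breaks symmetry.

## Trajectory analysis and selection

Angular velocity is recorded in rad/ms; steps with $|\omega|$ below the mask
are excluded and transitions are the steps where the remaining sign first
changes. Segments between consecutive transitions contribute their chord
length, arc-minus-chord difference (sinuosity), and direction; stability is
read from the signed angles between consecutive segment directions, the
first-to-last segment angle, and the trajectory angle (origin-to-final
direction against the initial heading — the two coincide at the start,
which resolves the reference ambiguity).

The six selection conditions are scored across the four symmetric input
levels (25/50/75/100 %): c1 transitions increase; c2 median segment length
decreases; c3 median sinuosity difference decreases; c4 |median intersegment
angle| ≤ 0.1 rad; c5 |first-last angle| ≤ 0.25 rad; c6 |trajectory angle| ≤
0.25 rad. Monotonicity is strict rank concordance (no step against the
trend, at least one with it); angle conditions take the worst case across
levels, with undefined angles (fewer than two transitions) imposing no
constraint. A genotype whose transitions vanish at the top input level
satisfies c1–c3 by the "transitions disappear" clause; this deliberately
lets genotypes that go straight at high input score 6/6.

Phenotype classification is an explicit heuristic in place of visual
inspection. Each run is labelled by fixed thresholds (stopping: final speed
< 5 % of `v_max`; chaos: net displacement < 10 % of path length with ≥ 8
transitions; loop: |cumulative heading| > 2π; curve: > π/2 with ≤ 1
transition; straight: ≤ 1 transition and chord/path > 0.9; otherwise
zig-zag); the genotype takes the modal run label, and zig-zag genotypes get
one of seven subtypes from the cross-level transition trends, the worst-case
trajectory angle, the pooled sinuosity ratio, and the low/high-input labels.
All thresholds are exposed as arguments; reference phenotype percentages for
this model family rested on visual curation and are treated as qualitative
references only.

## Sweep protocol and problem sizes

Each genotype runs a battery of five 2,000-step simulations (symmetric
25/50/75/100 % plus asymmetric 25 %/100 %), each with its own seed from a
deterministic schedule (`battery_seed()`), so sweeps are reproducible and
chunkable. A genotype is excluded when any symmetric run's CPG layer emits
fewer than 2 spikes, or any run's maximal output rate exceeds 60 spikes/s
(Core; 120 for the Comprehensive descending neurons). The rate statistic is
the largest spike count in a sliding 1-s window — the printed unit of the
rule; the σ = 50 ms spike-density peak is available as an alternative
(`rate_stat = "sdf"`) but reads instantaneous burst rate and would exclude
even the showcase genotype.

The packaged study sizes, chosen to keep a desk-scale run in minutes: the
full Core grid (5^8 = 390,625 genotypes) is enumerated but swept on a
uniformly random 1,000-genotype subsample; behavioural statistics of the
showcase genotype use 100 seeds per input condition; the noise-robustness
experiment runs the showcase-neighbourhood presets (`robustness_presets()`,
6 genotypes) at noise factors 0.1/1/5 with 100 repetitions per cell,
holding each genotype's initial state fixed so that across-repetition
variability isolates the noise term.

## Known discrepancies and limitations

* **Spontaneous output rate.** The O-neuron tonic drive was reportedly tuned
  to target a ~30 Hz spontaneous rate, but under this Euler scheme it yields
  43.5 Hz (closed form: 21 update steps from reset to threshold, plus the
  clamp and refractory steps). We report the derived value.
* **Exclusion statistics.** With the cap only ~16 Hz above that baseline,
  any appreciable E→O excitation trips the 60 spikes/s rule — in the
  asymmetric condition the contralaterally uninhibited O neuron exceeds it
  even at the smallest tabulated weight. The subsample exclusion fraction is
  therefore ~96 %, far above the 63.9 % reference value for the full grid,
  and the condition-selected set is dominated by weak-excitation genotypes
  whose trajectories are straight or stopped rather than zig-zagging. No
  value of the unprinted `g_unit` reconciles both exclusion rules with that
  reference; the acceptance script reports the measured statistics as they
  fall.
* **What the generator does not emulate.** Inputs are static currents; there
  is no sensory feedback loop, no physics (mass, slip), and no biological
  heterogeneity between the two sides beyond the seeded initial state.
  Passing tests therefore demonstrate properties of the idealized circuit,
  not of any closed-loop navigation behaviour.
* **Numerical edges.** Euler decays require τ > Δt (enforced); adaptation
  uses $A^p$ with $A \ge 0$ floored at zero; the heading is wrapped to
  (−π, π]; a simulation aborts with a diagnostic naming the neuron and step
  if the membrane potential overflows.
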