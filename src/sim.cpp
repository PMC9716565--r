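#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column layout of the neuron parameter matrix (kept in step with
// .neuron_matrix() on the R side).
enum NCol {
  CM = 0, G_LEAK, V_LEAK, V_TH, V_SPIKE, V_RESET, V_ADAPT,
  T_REFRACT, I0, G_ADAPT, DELTA_A, P_EXP, TAU_ADAPT, ADAPTING, I_EXT,
  N_NCOL
};

// Synapse matrix columns: pre, post (0-based), g_syn, V_rev, tau_syn.
enum SCol { PRE = 0, POST, G_SYN, V_REV, TAU_SYN, N_SCOL };

static inline double wrap_angle(double a) {
  // wrap to (-pi, pi]; avoids fmod (versioned symbol in recent glibc)
  return a - 2.0 * M_PI * std::ceil((a - M_PI) / (2.0 * M_PI));
}

// Forward-Euler simulation of an adapting LIF network with conductance-based
// synapses and multiplicative noise, optionally coupled step-by-step to
// non-spiking integrator actuators and planar kinematics.
//
// Per step, in fixed order: (1) synaptic currents from the previous step's S
// and V; (2) membrane update for all neurons not in the spike clamp or
// refractory hold; (3) threshold detection and spike bookkeeping (V_spike
// clamp, adaptation and synapse increments, spike time); (4) Euler decay of
// A and S; (5) actuator/kinematics update from this step's spikes.
//
// Spike clamp scheme: the crossing step takes V_spike; the following step
// takes V_reset; t_refract/dt further steps hold V_reset before integration
// resumes, so consecutive spikes are at least t_refract + 2*dt apart.
//
// embodiment: 0 = none, 1 = core differential drive, 2 = comprehensive
// split velocity/turning. act = (tau_act, gain, v_max, axle, turn_gain).
// motor_idx: 0-based neuron indices; core = (O_L, O_R); comprehensive =
// (V_L, V_R, IL_L, IL_R, CL_L, CL_R).
// [[Rcpp::export(name = ".sim_snn_cpp")]]
List sim_snn_cpp(NumericMatrix neurons, NumericMatrix synapses,
                 NumericVector V0,
                 double dt, int n_steps, double noise_scale,
                 int embodiment, NumericVector act, IntegerVector motor_idx,
                 bool record_traces) {
  const int n = neurons.nrow();
  const int m = synapses.nrow();
  if (neurons.ncol() != N_NCOL) stop("neuron matrix has wrong column count");
  if (m > 0 && synapses.ncol() != N_SCOL) stop("synapse matrix has wrong column count");
  if (dt <= 0 || n_steps < 1 || noise_scale < 0) stop("invalid simulation config");

  if (V0.size() != n) stop("V0 must have one entry per neuron");
  std::vector<double> V(n), A(n, 0.0), S(m, 0.0), I_syn(n, 0.0);
  std::vector<int> hold(n, 0);       // remaining V_reset steps (incl. assignment step)
  std::vector<bool> just_spiked(n, false); // V_spike clamp active this step
  std::vector<int> n_ref(n);
  for (int i = 0; i < n; ++i) {
    V[i] = V0[i];
    n_ref[i] = (int) std::lround(neurons(i, T_REFRACT) / dt);
  }
  // outgoing synapse lists per neuron
  std::vector<std::vector<int>> out(n);
  for (int j = 0; j < m; ++j) {
    int pre = (int) synapses(j, PRE);
    if (pre < 0 || pre >= n) stop("synapse pre index out of range");
    int post = (int) synapses(j, POST);
    if (post < 0 || post >= n) stop("synapse post index out of range");
    out[pre].push_back(j);
  }

  std::vector<std::vector<double>> spikes(n);

  NumericMatrix Vtr, Atr, Str;
  if (record_traces) {
    Vtr = NumericMatrix(n_steps + 1, n);
    Atr = NumericMatrix(n_steps + 1, n);
    if (m > 0) Str = NumericMatrix(n_steps + 1, m);
    for (int i = 0; i < n; ++i) { Vtr(0, i) = V[i]; Atr(0, i) = 0.0; }
  }

  // embodiment state
  double tau_act = 0, gain = 0, v_max = 0, axle = 1, turn_gain = 0;
  if (embodiment > 0) {
    tau_act = act[0]; gain = act[1]; v_max = act[2]; axle = act[3]; turn_gain = act[4];
  }
  double vL = 0, vR = 0;                    // core force integrators
  double vF = 0, tLl = 0, tLr = 0, tRl = 0, tRr = 0; // comp: forward + per-side turn
  double x = 0, y = 0, heading = 0;
  NumericMatrix traj;
  if (embodiment > 0) traj = NumericMatrix(n_steps, 6);

  const bool noisy = noise_scale > 0;

  for (int step = 1; step <= n_steps; ++step) {
    // (1) synaptic currents from previous-step S and V
    std::fill(I_syn.begin(), I_syn.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      int post = (int) synapses(j, POST);
      I_syn[post] += synapses(j, G_SYN) * S[j] * (synapses(j, V_REV) - V[post]);
    }

    // (2) membrane update
    for (int i = 0; i < n; ++i) {
      if (just_spiked[i]) {            // leave V_spike clamp -> V_reset hold
        just_spiked[i] = false;
        V[i] = neurons(i, V_RESET);
        hold[i] = n_ref[i];            // further held steps after this one
        continue;
      }
      if (hold[i] > 0) { hold[i]--; V[i] = neurons(i, V_RESET); continue; }
      double drive = neurons(i, G_LEAK) * (neurons(i, V_LEAK) - V[i])
        + neurons(i, I0) + neurons(i, I_EXT) + I_syn[i];
      if (neurons(i, ADAPTING) != 0.0 && A[i] > 0.0)
        drive += neurons(i, G_ADAPT) * std::pow(A[i], neurons(i, P_EXP))
                 * (neurons(i, V_ADAPT) - V[i]);
      double eta = noisy ? noise_scale * unif_rand() / dt : 0.0;
      V[i] += dt / neurons(i, CM) * drive * (1.0 + eta);
      if (!std::isfinite(V[i]))
        stop("membrane potential overflow at neuron %d, step %d", i + 1, step);
    }

    // (3) threshold detection + spike bookkeeping
    for (int i = 0; i < n; ++i) {
      if (hold[i] > 0 || just_spiked[i]) continue;
      if (V[i] >= neurons(i, V_TH)) {
        V[i] = neurons(i, V_SPIKE);
        just_spiked[i] = true;
        spikes[i].push_back(step * dt);
        A[i] += neurons(i, DELTA_A);
        for (int j : out[i]) S[j] += 0.1;
      }
    }

    // (4) decays (every step, all neurons/synapses)
    for (int i = 0; i < n; ++i) {
      A[i] *= (1.0 - dt / neurons(i, TAU_ADAPT));
      if (A[i] < 0) A[i] = 0;
    }
    for (int j = 0; j < m; ++j) S[j] *= (1.0 - dt / synapses(j, TAU_SYN));

    if (record_traces) {
      for (int i = 0; i < n; ++i) { Vtr(step, i) = V[i]; Atr(step, i) = A[i]; }
      for (int j = 0; j < m; ++j) Str(step, j) = S[j];
    }

    // (5) embodiment
    if (embodiment > 0) {
      double spk[6] = {0, 0, 0, 0, 0, 0};
      int nm = motor_idx.size();
      for (int k = 0; k < nm; ++k) {
        int i = motor_idx[k];
        if (!spikes[i].empty() && spikes[i].back() == step * dt) spk[k] = 1.0;
      }
      double omega = 0, speed = 0;
      double decay = 1.0 - dt / tau_act;
      if (embodiment == 1) {
        // O_L drives the RIGHT force integrator, O_R the LEFT (contralateral)
        vR = vR * decay + gain * spk[0];
        vL = vL * decay + gain * spk[1];
        if (vR > v_max) vR = v_max; if (vR < 0) vR = 0;
        if (vL > v_max) vL = v_max; if (vL < 0) vL = 0;
        omega = (vR - vL) / axle;
        speed = 0.5 * (vL + vR);
      } else {
        // forward integrator fed by both V neurons
        vF = vF * decay + gain * (spk[0] + spk[1]);
        if (vF > v_max) vF = v_max; if (vF < 0) vF = 0;
        // left motor centre: leftward <- IL_L, rightward <- CL_R
        // right motor centre: rightward <- IL_R, leftward <- CL_L
        tLl = tLl * decay + gain * spk[2]; if (tLl > v_max) tLl = v_max;
        tRr = tRr * decay + gain * spk[3]; if (tRr > v_max) tRr = v_max;
        tRl = tRl * decay + gain * spk[4]; if (tRl > v_max) tRl = v_max;
        tLr = tLr * decay + gain * spk[5]; if (tLr > v_max) tLr = v_max;
        double sideL = tLl - tLr, sideR = tRl - tRr; // signed, + = leftward
        omega = turn_gain * 0.5 * (sideL + sideR);
        speed = vF;
      }
      heading = wrap_angle(heading + omega * dt);
      x += speed * dt * std::cos(heading);
      y += speed * dt * std::sin(heading);
      traj(step - 1, 0) = step * dt;
      traj(step - 1, 1) = x;
      traj(step - 1, 2) = y;
      traj(step - 1, 3) = heading;
      traj(step - 1, 4) = omega;   // rad/s
      traj(step - 1, 5) = speed;
    }
  }

  List spk_out(n);
  for (int i = 0; i < n; ++i) spk_out[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  List res = List::create(
    _["spikes"] = spk_out,
    _["V"] = record_traces ? (SEXP) Vtr : R_NilValue,
    _["A"] = record_traces ? (SEXP) Atr : R_NilValue,
    _["S"] = (record_traces && m > 0) ? (SEXP) Str : R_NilValue,
    _["trajectory"] = embodiment > 0 ? (SEXP) traj : R_NilValue);
  return res;
}
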