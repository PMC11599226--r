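// Clock-driven simulation core for the excitatory/inhibitory spiking network.
//
// Per-step updates use exact exponential solutions of the membrane, synaptic
// current and calcium-trace ODEs, so results are robust to the step size dt.
// Spike propagation from a recurrent neuron to its targets carries a one-step
// (dt) delay, which makes the update order well defined; external input
// spikes are delivered in the step they occur.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Poisson-coded input raster: each of n_input neurons independently emits a
// Bernoulli(rate * dt) spike per step while sample k is held for
// steps_per_bin steps. Equivalent to drawing a Binomial(steps_per_bin, p)
// count per (neuron, bin) and placing the spikes uniformly without
// replacement. Uses R's RNG, so set.seed() controls it.
// [[Rcpp::export]]
List cpp_gen_input_raster(NumericVector rates, int steps_per_bin, int n_input,
                          double dt) {
  if (steps_per_bin <= 0) stop("steps_per_bin must be positive");
  if (n_input <= 0) stop("n_input must be positive");
  const int n_bins = rates.size();
  std::vector<int64_t> keys;  // step * n_input + neuron, for sorting
  std::vector<char> taken(steps_per_bin);
  for (int k = 0; k < n_bins; ++k) {
    const double p = rates[k] * dt;
    if (p < 0 || !R_finite(p)) stop("encoded rate must be finite and >= 0");
    if (p >= 1.0)
      stop("encoded rate * dt >= 1: rate %g is unresolvable at dt = %g",
           rates[k], dt);
    if (p == 0.0) continue;
    for (int j = 0; j < n_input; ++j) {
      const int cnt = (int)R::rbinom((double)steps_per_bin, p);
      if (cnt == 0) continue;
      std::fill(taken.begin(), taken.end(), 0);
      int placed = 0;
      while (placed < cnt) {  // rejection: cnt << steps_per_bin in practice
        int off = (int)(R::unif_rand() * steps_per_bin);
        if (off >= steps_per_bin) off = steps_per_bin - 1;
        if (!taken[off]) {
          taken[off] = 1;
          ++placed;
          keys.push_back((int64_t)((int64_t)k * steps_per_bin + off) *
                             n_input + j);
        }
      }
    }
  }
  std::sort(keys.begin(), keys.end());
  const R_xlen_t n = keys.size();
  IntegerVector step(n), neuron(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    step[i] = (int)(keys[i] / n_input);
    neuron[i] = (int)(keys[i] % n_input);
  }
  return List::create(_["step"] = step, _["neuron"] = neuron);
}

struct Edge {
  int post;
  double w;
};

static std::vector<std::vector<Edge>> adjacency(const LogicalMatrix &mask,
                                                const NumericMatrix &w,
                                                int post_offset) {
  const int npre = mask.nrow(), npost = mask.ncol();
  std::vector<std::vector<Edge>> adj(npre);
  for (int i = 0; i < npre; ++i)
    for (int j = 0; j < npost; ++j)
      if (mask(i, j)) adj[i].push_back({j + post_offset, w(i, j)});
  return adj;
}

// Main loop. Neuron indices are global and 0-based: excitatory 0..n_exc-1,
// inhibitory n_exc..n_exc+n_inh-1. Input spikes must be sorted by step.
// Weight matrices are oriented presynaptic x postsynaptic. w_ee is the only
// plastic projection and is returned (copied, then modified).
// [[Rcpp::export]]
List cpp_sim_run(int n_exc, int n_inh,
                 LogicalMatrix m_in, NumericMatrix w_in,
                 LogicalMatrix m_ee, NumericMatrix w_ee_in,
                 LogicalMatrix m_ei, NumericMatrix w_ei,
                 LogicalMatrix m_ie, NumericMatrix w_ie,
                 NumericVector vthr_in, NumericVector vmem_in,
                 NumericVector cfire_in, NumericVector isyn_e_in,
                 NumericVector isyn_i_in, IntegerVector ref_in,
                 IntegerVector in_step, IntegerVector in_neuron,
                 int n_steps, double dt, List prm) {
  const int N = n_exc + n_inh;
  const double R_m = prm["R"], C_m = prm["C"];
  const double vreset = prm["vreset"], tref = prm["tref"];
  const double tau_syn = prm["tau_syn"], alpha = prm["alpha"];
  const double tau_ip = prm["tau_ip"];
  const bool sdsp_on = prm["sdsp_on"], ip_on = prm["ip_on"];
  const double lr_sdsp = prm["lr_sdsp"], wmax = prm["wmax"];
  const double lr_thr = prm["lr_thr"];
  const double vthr_min = prm["vthr_min"], vthr_max = prm["vthr_max"];
  const double c_ip = prm["c_ip"], sigma = prm["sigma"];
  const bool ca_before = prm["ca_increment_before_ip"];
  const bool raw_cfire = prm["raw_cfire_compare"];
  const bool sdsp_refractory = prm["sdsp_during_refractory"];
  const int trace_neuron = prm.containsElementNamed("trace_neuron")
                               ? (int)prm["trace_neuron"] : -1;

  if (dt <= 0) stop("dt must be positive");
  if (n_steps < 0) stop("n_steps must be >= 0");
  const double tau_m = R_m * C_m;
  const double dm = std::exp(-dt / tau_m);
  const double ds = std::exp(-dt / tau_syn);
  const double dc = std::exp(-dt / tau_ip);
  const double gain = R_m * (1.0 - dm);      // steady-state gain per step
  const double kick = alpha / tau_syn;       // current jump per unit weight
  const int tref_steps = (int)std::lround(tref / dt);
  const double ca_target = raw_cfire ? c_ip : c_ip * tau_ip;
  const double ca_hi = (1.0 + sigma / 2.0) * ca_target;
  const double ca_lo = (1.0 - sigma / 2.0) * ca_target;

  // working copies of the state
  std::vector<double> vthr(vthr_in.begin(), vthr_in.end());
  std::vector<double> vmem(vmem_in.begin(), vmem_in.end());
  std::vector<double> cfire(cfire_in.begin(), cfire_in.end());
  std::vector<double> isyn_e(isyn_e_in.begin(), isyn_e_in.end());
  std::vector<double> isyn_i(isyn_i_in.begin(), isyn_i_in.end());
  std::vector<int> ref(ref_in.begin(), ref_in.end());
  if ((int)vthr.size() != N || (int)vmem.size() != N)
    stop("state vectors must have length n_exc + n_inh");

  NumericMatrix w_ee(clone(w_ee_in));

  // static adjacency; E->E kept as index pairs so weight updates hit w_ee
  std::vector<std::vector<Edge>> a_in = adjacency(m_in, w_in, 0);
  std::vector<std::vector<Edge>> a_ei = adjacency(m_ei, w_ei, n_exc);
  std::vector<std::vector<Edge>> a_ie = adjacency(m_ie, w_ie, 0);
  std::vector<std::vector<int>> a_ee(n_exc);
  for (int i = 0; i < n_exc; ++i)
    for (int j = 0; j < n_exc; ++j)
      if (m_ee(i, j)) a_ee[i].push_back(j);

  std::vector<int> spk_step, spk_id, prev_fired, cur_fired;
  long n_pot = 0, n_dep = 0, n_up = 0, n_down = 0;
  NumericVector trace(trace_neuron >= 0 ? n_steps : 0);

  R_xlen_t in_ptr = 0;
  const R_xlen_t n_in = in_step.size();

  for (int t = 0; t < n_steps; ++t) {
    // 1. exponential decay of synaptic currents and calcium traces.
    // Values decaying toward zero are flushed once physically negligible
    // (1e-30 A, 1e-15 of a spike count): subnormal doubles would otherwise
    // dominate the run time on x86.
    for (int i = 0; i < N; ++i) {
      isyn_e[i] = (isyn_e[i] < 1e-30) ? 0.0 : isyn_e[i] * ds;
      isyn_i[i] = (isyn_i[i] > -1e-30) ? 0.0 : isyn_i[i] * ds;
      cfire[i] = (cfire[i] < 1e-15) ? 0.0 : cfire[i] * dc;
    }
    // 2. external input spikes arriving this step
    while (in_ptr < n_in && in_step[in_ptr] == t) {
      const int j = in_neuron[in_ptr];
      for (const Edge &e : a_in[j]) isyn_e[e.post] += kick * e.w;
      ++in_ptr;
    }
    if (in_ptr < n_in && in_step[in_ptr] < t)
      stop("input raster is not sorted by step");
    // 3. recurrent spikes fired in the previous step
    for (int pre : prev_fired) {
      if (pre < n_exc) {
        for (int post : a_ee[pre]) {
          const double w_old = w_ee(pre, post);
          isyn_e[post] += kick * w_old;  // current uses the stored weight
          if (sdsp_on && (sdsp_refractory || ref[post] == 0)) {
            // learning thresholds synchronized at Vthr/2 (both equal)
            const double vl = 0.5 * vthr[post];
            const double v = vmem[post];  // sampled before this step's
                                          // integration, i.e. before the
                                          // arriving spike acts on Vmem
            if (v > vl) {
              w_ee(pre, post) = std::min(w_old + lr_sdsp, wmax);
              ++n_pot;
            } else if (v < vl) {
              w_ee(pre, post) = std::max(w_old - lr_sdsp, 0.0);
              ++n_dep;
            }
          }
        }
        for (const Edge &e : a_ei[pre]) isyn_e[e.post] += kick * e.w;
      } else {
        for (const Edge &e : a_ie[pre - n_exc]) isyn_i[e.post] -= kick * e.w;
      }
    }
    // 4. membrane integration (input current held constant over the step)
    for (int i = 0; i < N; ++i) {
      if (ref[i] > 0) {
        --ref[i];
        vmem[i] = vreset;
      } else {
        const double v = vmem[i] * dm + (isyn_e[i] + isyn_i[i]) * gain;
        vmem[i] = (v > -1e-15 && v < 1e-15) ? 0.0 : v;  // flush subnormals
      }
    }
    if (trace_neuron >= 0) trace[t] = vmem[trace_neuron];
    // 5. firing, reset, calcium increment, event-driven IP
    cur_fired.clear();
    for (int i = 0; i < N; ++i) {
      if (ref[i] == 0 && vmem[i] > vthr[i]) {  // strict: ties do not fire
        cur_fired.push_back(i);
        spk_step.push_back(t);
        spk_id.push_back(i);
        vmem[i] = vreset;
        ref[i] = tref_steps;
        if (ca_before) cfire[i] += 1.0;
        if (ip_on && i < n_exc) {
          if (cfire[i] > ca_hi) {
            vthr[i] = std::min(vthr[i] + lr_thr, vthr_max);
            ++n_up;
          } else if (cfire[i] < ca_lo) {
            vthr[i] = std::max(vthr[i] - lr_thr, vthr_min);
            ++n_down;
          }
        }
        if (!ca_before) cfire[i] += 1.0;
      }
    }
    std::swap(prev_fired, cur_fired);
    if ((t & 0x3FFF) == 0) {
      for (int i = 0; i < N; ++i)
        if (!R_finite(vmem[i]))
          stop("simulation diverged: non-finite membrane potential at step %d",
               t);
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < N; ++i)
    if (!R_finite(vmem[i]))
      stop("simulation diverged: non-finite membrane potential at step %d",
           n_steps);

  List out = List::create(
      _["spk_step"] = IntegerVector(spk_step.begin(), spk_step.end()),
      _["spk_neuron"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["w_ee"] = w_ee,
      _["vthr"] = NumericVector(vthr.begin(), vthr.end()),
      _["vmem"] = NumericVector(vmem.begin(), vmem.end()),
      _["cfire"] = NumericVector(cfire.begin(), cfire.end()),
      _["isyn_e"] = NumericVector(isyn_e.begin(), isyn_e.end()),
      _["isyn_i"] = NumericVector(isyn_i.begin(), isyn_i.end()),
      _["ref"] = IntegerVector(ref.begin(), ref.end()),
      _["events"] = NumericVector::create(
          _["pot"] = (double)n_pot, _["dep"] = (double)n_dep,
          _["thr_up"] = (double)n_up, _["thr_down"] = (double)n_down));
  if (trace_neuron >= 0) out["vmem_trace"] = trace;
  return out;
}
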