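// Fixed-step integrate-and-fire engine.
//
// Two neuron models share the engine:
//   model 0: current-based LIF with exponential postsynaptic currents
//            (hard reset + absolute refractory period)
//   model 1: conductance-based LIF with a spike-triggered
//            after-hyperpolarizing conductance instead of a hard reset
//
// Both use the exact exponential update for the membrane equation with
// inputs held constant over one step (so a constant injected current is
// integrated exactly, and spike times land on the step boundary after the
// true threshold crossing).
//
// Parameter matrix columns (n x 13), interpreted per model:
//   0: C_m [pF]
//   1: tau_m [ms]        (model 0)  | g_L [nS]   (model 1)
//   2: V_rest [mV]       (model 0)  | E_L [mV]   (model 1)
//   3: V_th [mV]
//   4: V_reset [mV]      (model 0 only)
//   5: t_ref [ms]        (model 0 only)
//   6: tau_syn_ex [ms]
//   7: tau_syn_in [ms]
//   8: E_ex [mV]         (model 1 only)
//   9: E_in [mV]         (model 1 only)
//  10: E_ahp [mV]        (model 1 only)
//  11: g_ahp [nS]        (model 1 only, per-spike AHP increment)
//  12: tau_ahp [ms]      (model 1 only)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct NeuronState {
  double V;
  double s_ex;   // pA (model 0) or nS (model 1)
  double s_in;   // pA (signed, model 0) or nS (positive, model 1)
  double g_ahp;  // nS, model 1 only
  int ref;       // remaining refractory steps, model 0 only
};

inline double lif_exp_vinf(double V_rest, double I_tot, double tau_m, double C_m) {
  return V_rest + I_tot * tau_m / C_m;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_network")]]
List cpp_simulate_network(IntegerVector model,
                          NumericMatrix params,
                          IntegerVector syn_ptr,
                          IntegerVector syn_post,
                          NumericVector syn_w,
                          IntegerVector syn_delay,
                          IntegerVector inj_row,
                          NumericMatrix inj_current,
                          NumericVector noise_rate,
                          NumericVector noise_w,
                          double duration,
                          double dt,
                          IntegerVector record_v,
                          double v_min = -120.0) {
  const int n = model.size();
  if (params.nrow() != n) stop("params must have one row per neuron");
  const int n_steps = (int) std::ceil(duration / dt - 1e-9);
  const int n_ms = inj_current.ncol();

  // per-neuron precomputed decay factors
  std::vector<double> e_m(n), e_ex(n), e_in(n), e_ahp(n);
  std::vector<int> ref_steps(n);
  for (int i = 0; i < n; ++i) {
    double tau_ex = params(i, 6), tau_in = params(i, 7);
    e_ex[i] = std::exp(-dt / tau_ex);
    e_in[i] = std::exp(-dt / tau_in);
    if (model[i] == 0) {
      e_m[i] = std::exp(-dt / params(i, 1));
      ref_steps[i] = (int) std::lround(params(i, 5) / dt);
      e_ahp[i] = 1.0;
    } else {
      e_m[i] = 0.0; // computed per step (g_tot varies)
      ref_steps[i] = 0;
      e_ahp[i] = std::exp(-dt / params(i, 12));
    }
  }

  std::vector<NeuronState> st(n);
  for (int i = 0; i < n; ++i) {
    st[i].V = params(i, 2);
    st[i].s_ex = 0.0; st[i].s_in = 0.0; st[i].g_ahp = 0.0; st[i].ref = 0;
  }

  // delay ring buffer
  int d_max = 1;
  for (int k = 0; k < syn_delay.size(); ++k)
    if (syn_delay[k] > d_max) d_max = syn_delay[k];
  std::vector< std::vector< std::pair<int, double> > > ring(d_max + 1);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_rec = record_v.size();
  NumericMatrix v_trace(n_rec, n_rec > 0 ? n_steps : 0);

  bool any_noise = false;
  for (int i = 0; i < n; ++i) if (noise_rate[i] > 0) { any_noise = true; break; }
  RNGScope rng_scope;

  for (int s = 0; s < n_steps; ++s) {
    const double t_end = (s + 1) * dt;
    const int slot = s % (d_max + 1);
    const int ms = std::min((int) std::floor(s * dt), n_ms - 1);

    // deliver due spikes
    for (size_t k = 0; k < ring[slot].size(); ++k) {
      const int tgt = ring[slot][k].first;
      const double w = ring[slot][k].second;
      if (w >= 0) st[tgt].s_ex += w; else {
        if (model[tgt] == 0) st[tgt].s_in += w; else st[tgt].s_in -= w;
      }
    }
    ring[slot].clear();

    // background Poisson excitatory events
    if (any_noise) {
      for (int i = 0; i < n; ++i) {
        if (noise_rate[i] <= 0) continue;
        double lam = noise_rate[i] * dt * 1e-3;
        int k = (int) R::rpois(lam);
        if (k > 0) st[i].s_ex += k * noise_w[i];
      }
    }

    for (int i = 0; i < n; ++i) {
      NeuronState &x = st[i];
      const double I_inj = (inj_row[i] >= 0 && ms < n_ms) ? inj_current(inj_row[i], ms) : 0.0;
      bool spiked = false;

      if (model[i] == 0) {
        if (x.ref > 0) {
          x.ref--;
          x.V = params(i, 4);
        } else {
          const double I_tot = x.s_ex + x.s_in + I_inj;
          const double vinf = lif_exp_vinf(params(i, 2), I_tot, params(i, 1), params(i, 0));
          x.V = vinf + (x.V - vinf) * e_m[i];
          if (x.V >= params(i, 3)) {
            spiked = true;
            x.V = params(i, 4);
            x.ref = ref_steps[i];
          }
        }
      } else {
        const double g_L = params(i, 1);
        const double g_tot = g_L + x.s_ex + x.s_in + x.g_ahp;
        const double vinf = (g_L * params(i, 2) + x.s_ex * params(i, 8) +
                             x.s_in * params(i, 9) + x.g_ahp * params(i, 10) +
                             I_inj) / g_tot;
        const double v_prev = x.V;
        x.V = vinf + (x.V - vinf) * std::exp(-dt * g_tot / params(i, 0));
        if (v_prev < params(i, 3) && x.V >= params(i, 3)) {
          spiked = true;
          x.g_ahp += params(i, 11);
        }
      }

      if (x.V < v_min) x.V = v_min;  // hyperpolarization floor
      if (x.V != x.V || std::fabs(x.V) > 200.0)
        stop("numerical blow-up: |V| > 200 mV or NaN at neuron %d, t = %.2f ms",
             i + 1, t_end);

      if (spiked) {
        spike_id.push_back(i + 1);
        spike_t.push_back(t_end);
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          const int dslot = (s + syn_delay[k]) % (d_max + 1);
          ring[dslot].push_back(std::make_pair(syn_post[k], syn_w[k]));
        }
      }

      // synaptic decay for next step
      x.s_ex *= e_ex[i];
      x.s_in *= e_in[i];
      x.g_ahp *= e_ahp[i];
    }

    for (int r = 0; r < n_rec; ++r)
      v_trace(r, s) = st[record_v[r]].V;
  }

  return List::create(_["id"] = wrap(spike_id),
                      _["time"] = wrap(spike_t),
                      _["v"] = v_trace,
                      _["n_steps"] = n_steps);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_neuron")]]
List cpp_simulate_neuron(int model,
                         NumericVector params,
                         NumericVector inj,      // pA per step (length >= n_steps), or length 0
                         IntegerVector arr_step, // 0-based step of arrival
                         NumericVector arr_w,    // signed weight (pA or nS)
                         double duration,
                         double dt,
                         double v_min = -120.0) {
  const int n_steps = (int) std::ceil(duration / dt - 1e-9);
  NumericVector V(n_steps);
  std::vector<double> spike_t;

  double v = params[2], s_ex = 0.0, s_in = 0.0, g_ahp = 0.0;
  int ref = 0;
  const double e_ex = std::exp(-dt / params[6]);
  const double e_in = std::exp(-dt / params[7]);
  const double e_m = (model == 0) ? std::exp(-dt / params[1]) : 0.0;
  const double e_ahp = (model == 1) ? std::exp(-dt / params[12]) : 1.0;
  const int ref_steps = (model == 0) ? (int) std::lround(params[5] / dt) : 0;

  int a = 0;
  const int n_arr = arr_step.size();

  for (int s = 0; s < n_steps; ++s) {
    while (a < n_arr && arr_step[a] == s) {
      const double w = arr_w[a];
      if (w >= 0) s_ex += w; else { if (model == 0) s_in += w; else s_in -= w; }
      ++a;
    }
    const double I_inj = (s < inj.size()) ? inj[s] : 0.0;
    if (I_inj != I_inj) stop("NaN in injected current at step %d", s + 1);

    if (model == 0) {
      if (ref > 0) {
        ref--;
        v = params[4];
      } else {
        const double I_tot = s_ex + s_in + I_inj;
        const double vinf = params[2] + I_tot * params[1] / params[0];
        v = vinf + (v - vinf) * e_m;
        if (v >= params[3]) {
          spike_t.push_back((s + 1) * dt);
          v = params[4];
          ref = ref_steps;
        }
      }
    } else {
      const double g_L = params[1];
      const double g_tot = g_L + s_ex + s_in + g_ahp;
      const double vinf = (g_L * params[2] + s_ex * params[8] + s_in * params[9] +
                           g_ahp * params[10] + I_inj) / g_tot;
      const double v_prev = v;
      v = vinf + (v - vinf) * std::exp(-dt * g_tot / params[0]);
      if (v_prev < params[3] && v >= params[3]) {
        spike_t.push_back((s + 1) * dt);
        g_ahp += params[11];
      }
    }

    if (v < v_min) v = v_min;  // hyperpolarization floor
    if (v != v || std::fabs(v) > 200.0)
      stop("numerical blow-up at step %d", s + 1);

    s_ex *= e_ex;
    s_in *= e_in;
    g_ahp *= e_ahp;
    V[s] = v;
  }

  return List::create(_["v"] = V, _["spikes"] = wrap(spike_t));
}
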