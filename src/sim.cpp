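#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core integrate-and-fire loop.
//
// State per neuron: membrane potential v (mV), excitatory and inhibitory
// synaptic variables ge >= 0 and gi <= 0 (mV), refractory countdown (ms).
// Per step (dt):
//   1. spikes emitted on the PREVIOUS step are delivered (one-step delay):
//      ge[target] += Ws(source) for excitatory/leader sources (Ws > 0),
//      gi[target] += Ws(source) for interneuron sources (Ws < 0);
//   2. field signals are sampled from this post-delivery snapshot:
//      lfp = mean over neurons of (-(v - v0) + ge + gi + dam) / tau_m,
//      vm_sum = sum of v;
//   3. membrane update: refractory neurons are clamped at vr and count
//      down; others relax toward v_inf = v0 + dam + ge + gi, exactly for
//      the linear drift (exponential Euler) or by forward Euler;
//      crossing vt fires, resets to vr and starts the refractory window;
//   4. ge and gi decay by exp(-dt/tau_e), exp(-dt/tau_i).
//
// Connectivity is CSR by source: src_ptr (n+1, 0-based offsets) and
// targets (0-based). All outgoing edges of a source share its Ws.
// [[Rcpp::export]]
List run_sim_cpp(const int n,
                 const IntegerVector& src_ptr,
                 const IntegerVector& targets,
                 const NumericVector& w_src,
                 const NumericVector& v0,
                 const NumericVector& dam,
                 const NumericVector& tau_m,
                 const NumericVector& v_init,
                 const double dt,
                 const int n_steps,
                 const double vt,
                 const double vr,
                 const double refractory,
                 const double tau_e,
                 const double tau_i,
                 const bool euler,
                 const bool delta_syn,
                 const double v_floor,
                 const bool record_state) {
  const bool has_floor = std::isfinite(v_floor);
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> ge(n, 0.0), gi(n, 0.0), refrac(n, 0.0);
  std::vector<double> em(n);
  for (int j = 0; j < n; ++j) em[j] = std::exp(-dt / tau_m[j]);
  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);

  std::vector<int> fired_prev, fired;
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(4096);
  sp_t.reserve(4096);
  NumericVector lfp(n_steps), vm(n_steps);
  NumericMatrix vh, geh, gih;
  if (record_state) {
    vh = NumericMatrix(n_steps, n);
    geh = NumericMatrix(n_steps, n);
    gih = NumericMatrix(n_steps, n);
  }

  for (int s = 0; s < n_steps; ++s) {
    for (size_t k = 0; k < fired_prev.size(); ++k) {
      const int i = fired_prev[k];
      const double w = w_src[i];
      if (delta_syn) {
        // impulse synapse: the weight perturbs V directly and then decays
        // at the *membrane* constant of the target; refractory-clamped
        // targets do not integrate input
        for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) {
          const int j = targets[e];
          if (refrac[j] <= 0.0) {
            v[j] += w;
            if (has_floor && v[j] < v_floor) v[j] = v_floor;
          }
        }
      } else if (w > 0.0) {
        for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) ge[targets[e]] += w;
      } else {
        for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) gi[targets[e]] += w;
      }
    }

    double acc = 0.0, vsum = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += (-(v[j] - v0[j]) + ge[j] + gi[j] + dam[j]) / tau_m[j];
      vsum += v[j];
    }
    lfp[s] = acc / n;
    vm[s] = vsum;
    if (record_state) {
      for (int j = 0; j < n; ++j) {
        vh(s, j) = v[j];
        geh(s, j) = ge[j];
        gih(s, j) = gi[j];
      }
    }

    fired.clear();
    for (int j = 0; j < n; ++j) {
      if (refrac[j] > 0.0) {
        v[j] = vr;
        refrac[j] -= dt;
        if (refrac[j] < 0.0) refrac[j] = 0.0;
      } else {
        const double vinf = v0[j] + dam[j] + ge[j] + gi[j];
        if (euler) {
          v[j] += dt * (vinf - v[j]) / tau_m[j];
        } else {
          v[j] = vinf + (v[j] - vinf) * em[j];
        }
        if (!std::isfinite(v[j]))
          stop("non-finite membrane potential: neuron %d, step %d", j + 1, s + 1);
        // damaged (synaptically silent) neurons cannot initiate spikes even
        // if a synchronized volley of EPSPs transiently crosses threshold
        if (v[j] >= vt && dam[j] == 0.0) {
          fired.push_back(j);
          sp_id.push_back(j + 1);
          sp_t.push_back((s + 1) * dt);
          v[j] = vr;
          refrac[j] = refractory;
        }
      }
      ge[j] *= de;
      gi[j] *= di;
    }
    fired_prev = fired;
  }

  List out = List::create(
    _["neuron_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["time_ms"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["lfp"] = lfp,
    _["vm_sum"] = vm,
    _["v_final"] = NumericVector(v.begin(), v.end()));
  if (record_state) {
    out["v_hist"] = vh;
    out["ge_hist"] = geh;
    out["gi_hist"] = gih;
  }
  return out;
}
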