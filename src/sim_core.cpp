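#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Forward-Euler integration of the antennal lobe network.
//
// Conductance states are single decaying accumulators: each synaptic or
// external event adds a jump S/tau and the state decays by the exact factor
// exp(-dt/tau) per step (identical to the alpha-kernel sum). The membrane
// potential uses plain Euler. The SK conductance uses the sigmoidal-rise
// kernel literally for spike ages within the rise window (precomputed
// table) and folds older spikes into one exponential accumulator, which is
// exact because the kernel is a pure exponential beyond 2*tau_rise.
//
// Event timing conventions (documented in the package vignette):
//  * external events in bin k act on the step-k membrane update;
//  * a spike fired at step k reaches its postsynaptic targets at step k+1;
//  * a PN's own spike at step k enters its SK sum from step k+1 (age dt).
//
// [[Rcpp::export]]
List sim_core(IntegerVector cls,           // 0 = PN, 1 = LN
              NumericVector sk_strength,   // per neuron (0 for LN)
              IntegerVector adj_ptr,       // CSR over presynaptic neurons
              IntegerVector adj_tgt,       // 0-based postsynaptic ids
              List par,                    // scalar constants, see R caller
              NumericMatrix rates,         // groups x steps, spikes/ms
              IntegerVector group,         // 0-based group per neuron
              int n_steps,
              double dt,
              NumericVector v_init,
              IntegerVector record,        // 0-based neuron ids to trace
              IntegerMatrix ext_counts,    // optional fixed input (0 rows = off)
              double stim_clamp,           // >= 0: hold g_stim at this value
              bool return_inputs) {
  const int n = cls.size();
  const double tau_V = par["tau_V"], V_L = par["V_L"],
               V_thres = par["V_thres"], tau_ref = par["tau_ref"],
               V_exc = par["V_exc"], V_stim = par["V_stim"],
               V_inh = par["V_inh"], V_SK = par["V_SK"],
               tau_exc = par["tau_exc"], tau_inh = par["tau_inh"],
               tau_stim = par["tau_stim"], tau_slow = par["tau_slow"],
               tau_SK = par["tau_SK"], tau_rise = par["tau_SK_rise"];
  const double jump_exc[2] = {
    (double)par["scale_exc"] * (double)par["S_PN_to_PN"] / tau_exc,
    (double)par["scale_exc"] * (double)par["S_PN_to_LN"] / tau_exc };
  const double jump_inh[2] = {
    (double)par["scale_inh"] * (double)par["S_inh_PN"] / tau_inh,
    (double)par["scale_inh"] * (double)par["S_inh_LN"] / tau_inh };
  const double jump_slow[2] = {
    (double)par["scale_slow"] * (double)par["S_slow_PN"] / tau_slow,
    (double)par["scale_slow"] * (double)par["S_slow_LN"] / tau_slow };
  const double jump_stim[2] = {
    (double)par["scale_stim"] * (double)par["S_stim_PN"] / tau_stim,
    (double)par["scale_stim"] * (double)par["S_stim_LN"] / tau_stim };

  const double d_exc = std::exp(-dt / tau_exc), d_inh = std::exp(-dt / tau_inh),
               d_stim = std::exp(-dt / tau_stim),
               d_slow = std::exp(-dt / tau_slow),
               d_sk = std::exp(-dt / tau_SK);
  const int refr_steps = (int)std::lround(tau_ref / dt);
  const int n_sig = (int)std::floor(2.0 * tau_rise / dt + 1e-9);
  const double inv_tauSK = 1.0 / tau_SK;

  // sigmoid branch of the SK kernel, ages 1..n_sig in steps
  std::vector<double> sigtab(n_sig + 1, 0.0);
  for (int a = 1; a <= n_sig; ++a) {
    double u = a * dt;
    double z = 5.0 * (u - tau_rise) / tau_rise;
    sigtab[a] = inv_tauSK * (1.0 / (1.0 + std::exp(-z)));
  }

  std::vector<double> V(n), g_exc(n, 0.0), g_inh(n, 0.0), g_slow(n, 0.0),
      g_stim(n, 0.0), sk_tail(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<std::deque<int> > young(n);
  for (int i = 0; i < n; ++i) V[i] = v_init[i % v_init.size()];
  const bool clamp = stim_clamp >= 0.0;
  if (clamp) for (int i = 0; i < n; ++i) g_stim[i] = stim_clamp;
  const bool have_ext = ext_counts.nrow() > 0;

  std::vector<int> spikers_prev, spikers_now;
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(4096);
  spike_t.reserve(4096);

  const int n_rec = record.size();
  NumericMatrix tr_V, tr_exc, tr_inh, tr_slow, tr_stim, tr_sk;
  if (n_rec > 0) {
    tr_V = NumericMatrix(n_steps, n_rec);
    tr_exc = NumericMatrix(n_steps, n_rec);
    tr_inh = NumericMatrix(n_steps, n_rec);
    tr_slow = NumericMatrix(n_steps, n_rec);
    tr_stim = NumericMatrix(n_steps, n_rec);
    tr_sk = NumericMatrix(n_steps, n_rec);
  }
  IntegerMatrix ext_out;
  if (return_inputs) ext_out = IntegerMatrix(n, n_steps);

  RNGScope rng;

  for (int k = 1; k <= n_steps; ++k) {
    // 1. exact kernel decay; migrate aged SK spikes into the tail
    for (int i = 0; i < n; ++i) {
      g_exc[i] *= d_exc;
      g_inh[i] *= d_inh;
      g_slow[i] *= d_slow;
      if (!clamp) g_stim[i] *= d_stim;
      if (cls[i] == 0) {
        sk_tail[i] *= d_sk;
        std::deque<int>& yq = young[i];
        while (!yq.empty() && k - yq.front() > n_sig) {
          // age is exactly n_sig + 1 here (checked every step)
          sk_tail[i] += inv_tauSK * d_sk;
          yq.pop_front();
        }
      }
    }
    // 2. external Poisson (or canned) input events for this bin
    if (!clamp) {
      for (int i = 0; i < n; ++i) {
        int c;
        if (have_ext) {
          c = ext_counts(i, k - 1);
        } else {
          double lam = rates(group[i], k - 1) * dt;
          if (lam < 0) stop("internal error: negative input rate at step %d", k);
          c = (int)R::rpois(lam);
        }
        if (c > 0) g_stim[i] += c * jump_stim[cls[i]];
        if (return_inputs) ext_out(i, k - 1) = c;
      }
    }
    // 3. synaptic jumps from spikes of the previous step
    for (size_t s = 0; s < spikers_prev.size(); ++s) {
      int pre = spikers_prev[s];
      bool pre_pn = cls[pre] == 0;
      for (int e = adj_ptr[pre]; e < adj_ptr[pre + 1]; ++e) {
        int post = adj_tgt[e];
        if (pre_pn) {
          g_exc[post] += jump_exc[cls[post]];
        } else {
          g_inh[post] += jump_inh[cls[post]];
          g_slow[post] += jump_slow[cls[post]];
        }
      }
    }
    // 4.-5. SK evaluation and Euler membrane update
    spikers_now.clear();
    for (int i = 0; i < n; ++i) {
      double gsk = 0.0;
      if (cls[i] == 0 && sk_strength[i] > 0) {
        double ker = sk_tail[i];
        const std::deque<int>& yq = young[i];
        for (size_t q = 0; q < yq.size(); ++q) ker += sigtab[k - yq[q]];
        gsk = sk_strength[i] * ker;
      }
      double v = V[i];
      if (refr[i] > 0) {
        --refr[i];
        v = V_L;
      } else {
        double dv = -(v - V_L) / tau_V
                    - g_stim[i] * (v - V_stim)
                    - g_exc[i] * (v - V_exc)
                    - g_inh[i] * (v - V_inh)
                    - g_slow[i] * (v - V_inh)
                    - gsk * (v - V_SK);
        v += dt * dv;
        if (!std::isfinite(v)) {
          stop("non-finite membrane potential: neuron %d at step %d", i + 1, k);
        }
        if (v >= V_thres) {
          spike_id.push_back(i + 1);
          spike_t.push_back(k * dt);
          spikers_now.push_back(i);
          if (cls[i] == 0) young[i].push_back(k);
          v = V_L;
          refr[i] = refr_steps;
        }
      }
      V[i] = v;
      if (n_rec > 0) {
        for (int r = 0; r < n_rec; ++r) {
          if (record[r] == i) {
            tr_V(k - 1, r) = v;
            tr_exc(k - 1, r) = g_exc[i];
            tr_inh(k - 1, r) = g_inh[i];
            tr_slow(k - 1, r) = g_slow[i];
            tr_stim(k - 1, r) = g_stim[i];
            tr_sk(k - 1, r) = gsk;
          }
        }
      }
    }
    spikers_prev.swap(spikers_now);
  }

  List out = List::create(
      _["spike_id"] = wrap(spike_id),
      _["spike_t"] = wrap(spike_t));
  if (n_rec > 0) {
    out["traces"] = List::create(
        _["V"] = tr_V, _["g_exc"] = tr_exc, _["g_inh"] = tr_inh,
        _["g_slow"] = tr_slow, _["g_stim"] = tr_stim, _["g_SK"] = tr_sk);
  }
  if (return_inputs) out["ext_counts"] = ext_out;
  return out;
}
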