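// Stochastic-Heun integrator for sparse networks of Izhikevich / AdEx neurons
// with conductance-based synapses and Ornstein-Uhlenbeck conductance noise.
//
// Conventions:
//  - time in ms, voltage in mV; model currents / recovery variable are the
//    dimensionless quantities of the Izhikevich formalism.
//  - conductances follow dG = -G/tau dt + sqrt(2 D n) dW between presynaptic
//    spikes; each presynaptic spike adds the increment g_ex / g_in one
//    integration step after threshold crossing; G is reflected at zero.
//  - spikes are detected at the end of the corrector stage (v >= v_peak),
//    recorded with v clamped to v_peak, then the fire-and-reset rule applies.
//
// All inputs are copied to contiguous std::vector buffers up front; the hot
// loop touches no R objects.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct VoltageField {
  // shared Izhikevich voltage-equation constants
  double alpha, beta, gamma;
  // AdEx constants (used when model == 1)
  double gL, DeltaT, vT, offset;
  int model; // 0 = izhikevich, 1 = adex

  inline double dv(double v, double u, double I, double EL) const {
    if (model == 0) {
      return alpha * v * v + beta * v + gamma - u + I;
    }
    return -gL * (v - EL) + gL * DeltaT * std::exp((v - vT) / DeltaT) +
           offset - u + I;
  }
};

inline double reflect0(double x) { return x < 0.0 ? -x : x; }

template <typename T, typename S> std::vector<T> as_vec(const S &x) {
  return std::vector<T>(x.begin(), x.end());
}

} // namespace

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(
    IntegerVector adj_targets_, // concatenated postsynaptic targets (0-based)
    IntegerVector adj_offsets_, // length N+1, CSR offsets into adj_targets
    LogicalVector is_exc_,      // per-neuron excitatory flag (presynaptic role)
    NumericVector a_, NumericVector b_, NumericVector c_, NumericVector d_,
    double alpha, double beta, double gamma, double v_peak,
    int model,                  // 0 izhikevich, 1 adex
    double adex_gL, double adex_DeltaT, double adex_vT, double adex_offset,
    double g_ex, double g_in, double tau_ex, double tau_in,
    double E_ex, double E_in,
    double D,
    IntegerVector n_ex_, IntegerVector n_in_, // in-degrees (noise scaling)
    bool reflect,
    NumericVector I_stim_,      // per-neuron stimulation amplitude
    double t_stim,              // stimulation switched off at t >= t_stim
    NumericVector v0, NumericVector u0,
    double t_end, double dt, double record_interval,
    IntegerVector record_ids_,  // 0-based neuron ids with full traces
    int seed) {

  const int N = a_.size();
  const int n_steps = (int)std::llround(t_end / dt);
  const int rec_every = std::max(1, (int)std::llround(record_interval / dt));
  const int n_rec = n_steps / rec_every;
  const int n_tr = record_ids_.size();

  const VoltageField F{alpha, beta, gamma, adex_gL, adex_DeltaT, adex_vT,
                       adex_offset, model};

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);

  const std::vector<int> adj_targets = as_vec<int>(adj_targets_);
  const std::vector<int> adj_offsets = as_vec<int>(adj_offsets_);
  const std::vector<int> is_exc = as_vec<int>(is_exc_);
  const std::vector<double> a = as_vec<double>(a_), b = as_vec<double>(b_),
                            c = as_vec<double>(c_), d = as_vec<double>(d_),
                            I_stim = as_vec<double>(I_stim_);
  const std::vector<int> record_ids = as_vec<int>(record_ids_);

  std::vector<double> v = as_vec<double>(v0), u = as_vec<double>(u0);
  std::vector<double> Gex(N, 0.0), Gin(N, 0.0);
  std::vector<double> pend_ex(N, 0.0), pend_in(N, 0.0); // jumps for next step
  std::vector<double> sig_ex(N), sig_in(N);             // sqrt(2 D n) * sqrt(dt)
  const double sdt = std::sqrt(dt);
  for (int j = 0; j < N; ++j) {
    sig_ex[j] = std::sqrt(2.0 * D * (double)n_ex_[j]) * sdt;
    sig_in[j] = std::sqrt(2.0 * D * (double)n_in_[j]) * sdt;
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  long long reset_count = 0;

  std::vector<double> t_rec(n_rec), mean_v(n_rec), mean_u(n_rec);
  std::vector<double> tr_v((size_t)n_rec * n_tr), tr_u((size_t)n_rec * n_tr),
      tr_gex((size_t)n_rec * n_tr), tr_gin((size_t)n_rec * n_tr);

  std::vector<int> spiked;
  spiked.reserve(64);
  double last_spike_time = NA_REAL;
  bool blew_up = false;
  double blow_t = 0.0;
  const bool noisy = D > 0.0;

  for (int step = 0; step < n_steps && !blew_up; ++step) {
    const double t = step * dt;
    const bool stim_on = t < t_stim;

    for (int j = 0; j < N; ++j) {
      // Wiener increments, shared by predictor and corrector (additive
      // noise); components with zero in-degree receive no stochastic term
      double dWex = 0.0, dWin = 0.0;
      if (noisy) {
        if (sig_ex[j] > 0.0) dWex = sig_ex[j] * norm(rng);
        if (sig_in[j] > 0.0) dWin = sig_in[j] * norm(rng);
      }
      const double Iext = stim_on ? I_stim[j] : 0.0;

      // predictor (Euler)
      const double I0 = Gex[j] * (E_ex - v[j]) + Gin[j] * (E_in - v[j]) + Iext;
      const double fv0 = F.dv(v[j], u[j], I0, c[j]);
      const double fu0 = a[j] * (b[j] * v[j] - u[j]);
      double vp = v[j] + dt * fv0;
      const double up = u[j] + dt * fu0;
      const double Gexp = Gex[j] - dt * Gex[j] / tau_ex + dWex;
      const double Ginp = Gin[j] - dt * Gin[j] / tau_in + dWin;
      if (vp > v_peak) vp = v_peak; // avoid quadratic/exponential blow-up

      // corrector (trapezoidal, same Wiener increment)
      const double I1 = Gexp * (E_ex - vp) + Ginp * (E_in - vp) + Iext;
      const double fv1 = F.dv(vp, up, I1, c[j]);
      const double fu1 = a[j] * (b[j] * vp - up);
      v[j] += 0.5 * dt * (fv0 + fv1);
      u[j] += 0.5 * dt * (fu0 + fu1);
      Gex[j] += -0.5 * dt * (Gex[j] + Gexp) / tau_ex + dWex + pend_ex[j];
      Gin[j] += -0.5 * dt * (Gin[j] + Ginp) / tau_in + dWin + pend_in[j];
      pend_ex[j] = 0.0;
      pend_in[j] = 0.0;
      if (reflect) {
        Gex[j] = reflect0(Gex[j]);
        Gin[j] = reflect0(Gin[j]);
      }
    }

    const double t_now = t + dt;

    // recording (v clamped at the spike cutoff, before reset)
    if ((step + 1) % rec_every == 0) {
      const int k = (step + 1) / rec_every - 1;
      double sv = 0.0, su = 0.0;
      for (int j = 0; j < N; ++j) {
        sv += std::min(v[j], v_peak);
        su += u[j];
      }
      t_rec[k] = t_now;
      mean_v[k] = sv / N;
      mean_u[k] = su / N;
      for (int q = 0; q < n_tr; ++q) {
        const int j = record_ids[q];
        tr_v[(size_t)q * n_rec + k] = std::min(v[j], v_peak);
        tr_u[(size_t)q * n_rec + k] = u[j];
        tr_gex[(size_t)q * n_rec + k] = Gex[j];
        tr_gin[(size_t)q * n_rec + k] = Gin[j];
      }
    }

    // spike detection, reset and delivery scheduling
    spiked.clear();
    for (int j = 0; j < N; ++j) {
      if (v[j] >= v_peak) {
        spiked.push_back(j);
      } else if (std::fabs(v[j]) > 500.0 || !std::isfinite(v[j])) {
        blew_up = true;
        blow_t = t_now;
      }
    }
    for (int j : spiked) {
      spike_t.push_back(t_now);
      spike_id.push_back(j);
      ++reset_count;
      last_spike_time = t_now;
      v[j] = c[j];
      u[j] += d[j];
      if (is_exc[j]) {
        for (int e = adj_offsets[j]; e < adj_offsets[j + 1]; ++e)
          pend_ex[adj_targets[e]] += g_ex;
      } else {
        for (int e = adj_offsets[j]; e < adj_offsets[j + 1]; ++e)
          pend_in[adj_targets[e]] += g_in;
      }
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  if (blew_up)
    stop("numeric blow-up (|v| > 500 mV) at t = %f ms; reduce dt", blow_t);

  NumericMatrix m_v(n_rec, n_tr), m_u(n_rec, n_tr), m_gex(n_rec, n_tr),
      m_gin(n_rec, n_tr);
  if (n_tr > 0) {
    std::copy(tr_v.begin(), tr_v.end(), m_v.begin());
    std::copy(tr_u.begin(), tr_u.end(), m_u.begin());
    std::copy(tr_gex.begin(), tr_gex.end(), m_gex.begin());
    std::copy(tr_gin.begin(), tr_gin.end(), m_gin.begin());
  }

  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["t"] = NumericVector(t_rec.begin(), t_rec.end()),
      _["mean_v"] = NumericVector(mean_v.begin(), mean_v.end()),
      _["mean_u"] = NumericVector(mean_u.begin(), mean_u.end()),
      _["trace_v"] = m_v, _["trace_u"] = m_u,
      _["trace_gex"] = m_gex, _["trace_gin"] = m_gin,
      _["reset_count"] = (double)reset_count,
      _["last_spike_time"] = last_spike_time);
}

// First spike time of an isolated neuron at rest, driven only by
// Ornstein-Uhlenbeck conductance fluctuations (reflected at zero).
// Returns one time per trial; NA when no spike occurred before t_max.
// [[Rcpp::export(name = ".first_spike_cpp")]]
NumericVector first_spike_cpp(
    double a, double b, double c, double d,
    double alpha, double beta, double gamma, double v_peak,
    int model, double adex_gL, double adex_DeltaT, double adex_vT,
    double adex_offset,
    double tau_ex, double tau_in, double E_ex, double E_in,
    double D, double n_deg,
    double v_rest, double u_rest,
    int n_trials, double t_max, double dt, int seed) {

  const VoltageField F{alpha, beta, gamma, adex_gL, adex_DeltaT, adex_vT,
                       adex_offset, model};
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);

  const double sig = std::sqrt(2.0 * D * n_deg);
  const double sdt = std::sqrt(dt);
  const int n_steps = (int)std::llround(t_max / dt);
  NumericVector out(n_trials, NA_REAL);

  for (int tr = 0; tr < n_trials; ++tr) {
    double v = v_rest, u = u_rest, Gex = 0.0, Gin = 0.0;
    for (int step = 0; step < n_steps; ++step) {
      const double dWex = sig * sdt * norm(rng);
      const double dWin = sig * sdt * norm(rng);
      const double I0 = Gex * (E_ex - v) + Gin * (E_in - v);
      const double fv0 = F.dv(v, u, I0, c);
      const double fu0 = a * (b * v - u);
      double vp = v + dt * fv0;
      const double up = u + dt * fu0;
      const double Gexp = Gex - dt * Gex / tau_ex + dWex;
      const double Ginp = Gin - dt * Gin / tau_in + dWin;
      if (vp > v_peak) vp = v_peak;
      const double I1 = Gexp * (E_ex - vp) + Ginp * (E_in - vp);
      v += 0.5 * dt * (fv0 + F.dv(vp, up, I1, c));
      u += 0.5 * dt * (fu0 + a * (b * vp - up));
      Gex += -0.5 * dt * (Gex + Gexp) / tau_ex + dWex;
      Gin += -0.5 * dt * (Gin + Ginp) / tau_in + dWin;
      Gex = reflect0(Gex);
      Gin = reflect0(Gin);
      if (v >= v_peak) {
        out[tr] = (step + 1) * dt;
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
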