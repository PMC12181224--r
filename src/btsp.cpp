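#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Full BTSP session: leaky-integrator neuron on a circular track with
// spatially tuned Bernoulli inputs, plateau inductions, dual-source calcium
// (local presynaptic + globally broadcast plateau calcium, both decaying with
// tau_Ca) and 1D FPLR weight updates per synapse.
//
// Spikes are drawn with R's RNG (honours set.seed()) in a fixed (step,
// synapse) order unless a precomputed 0/1 spike matrix is supplied.
// [[Rcpp::export]]
List btsp_simulate_cpp(int laps, int steps_per_lap, double dt,
                       IntegerVector ind_lap, NumericVector ind_time,
                       int N, double r, double P_max, double track_T,
                       double V_rest, double V_plateau, double tau_V,
                       double C_m, double syn_scale,
                       double pre_height, double plateau_height,
                       double plateau_duration, double tau_Ca,
                       double theta_d, double theta_p,
                       NumericVector w0,
                       double F_d, double F_p, double eta_d, double eta_p,
                       double eta_pre, double F_pre,
                       IntegerVector record_idx,
                       Nullable<IntegerMatrix> spikes_in) {
  const R_xlen_t n_steps = (R_xlen_t)laps * steps_per_lap;
  const double decay_ca = std::exp(-dt / tau_Ca);
  const double decay_v = std::exp(-dt / tau_V);

  // receptive-field centers tile the track every track_T / N ms
  std::vector<double> centers(N);
  for (int i = 0; i < N; ++i) centers[i] = i * track_T / N;

  // rate lookup by circular distance when centers sit on the dt grid
  bool on_grid = true;
  for (int i = 0; i < N; ++i) {
    double k = centers[i] / dt;
    if (std::fabs(k - std::llround(k)) > 1e-9) { on_grid = false; break; }
  }
  std::vector<double> rate_tab;
  std::vector<long long> center_step(N);
  if (on_grid) {
    rate_tab.resize(steps_per_lap);
    for (int k = 0; k < steps_per_lap; ++k) {
      double d = k * dt;
      double circ = std::min(d, track_T - d);
      rate_tab[k] = P_max * std::exp(-(circ * circ) / (r * r));
    }
    for (int i = 0; i < N; ++i) center_step[i] = std::llround(centers[i] / dt);
  }

  // plateau activity per step
  std::vector<bool> plateau(n_steps, false);
  for (R_xlen_t j = 0; j < ind_lap.size(); ++j) {
    R_xlen_t s0 = (R_xlen_t)(ind_lap[j] - 1) * steps_per_lap
                  + (R_xlen_t)std::llround(ind_time[j] / dt);
    R_xlen_t len = (R_xlen_t)std::llround(plateau_duration / dt);
    for (R_xlen_t s = s0; s < s0 + len && s < n_steps; ++s) plateau[s] = true;
  }

  bool have_spikes = spikes_in.isNotNull();
  IntegerMatrix spk_mat;
  if (have_spikes) spk_mat = IntegerMatrix(spikes_in);

  int n_rec = record_idx.size();
  std::vector<int> rec(n_rec);
  std::vector<int> rec_of(N, -1);
  for (int j = 0; j < n_rec; ++j) {
    rec[j] = record_idx[j] - 1;
    rec_of[rec[j]] = j;
  }

  NumericVector voltage(n_steps);
  NumericMatrix w_rec(n_rec, n_steps), ca_rec(n_rec, n_steps);
  NumericMatrix dwell_d(N, laps), dwell_p(N, laps);
  IntegerVector spike_count(N);
  std::vector<std::vector<double> > rec_spikes(n_rec);

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> ca_pre(N, 0.0);
  std::vector<int> spikes(N, 0);
  double ca_plat = 0.0;
  double V = V_rest;

  for (R_xlen_t s = 0; s < n_steps; ++s) {
    int lap = (int)(s / steps_per_lap);
    int s_lap = (int)(s % steps_per_lap);
    double loc = s_lap * dt;

    // presynaptic spikes
    double syn_in = 0.0;
    for (int i = 0; i < N; ++i) {
      double rate;
      if (have_spikes) {
        spikes[i] = spk_mat(i, s);
        rate = 0.0;
      } else {
        if (on_grid) {
          long long dd = center_step[i] - s_lap;
          if (dd < 0) dd = -dd;
          if (dd >= steps_per_lap) dd = dd % steps_per_lap;
          rate = rate_tab[(size_t)dd];
        } else {
          double d = std::fabs(centers[i] - loc);
          double circ = std::min(d, track_T - d);
          rate = P_max * std::exp(-(circ * circ) / (r * r));
        }
        spikes[i] = (unif_rand() < rate) ? 1 : 0;
      }
      if (spikes[i]) {
        ++spike_count[i];
        syn_in += w[i];
        if (rec_of[i] >= 0) rec_spikes[rec_of[i]].push_back(s * dt);
      }
    }

    // plateau calcium: rectangular while active, exponential decay after
    if (plateau[s]) ca_plat = plateau_height;
    else ca_plat *= decay_ca;

    // per-synapse calcium and weight update
    for (int i = 0; i < N; ++i) {
      ca_pre[i] = ca_pre[i] * decay_ca + pre_height * spikes[i];
      double ca = ca_pre[i] + ca_plat;
      if (ca >= theta_p) {
        w[i] += eta_p * (F_p - w[i]);
        dwell_p(i, lap) += dt;
      } else if (ca >= theta_d) {
        w[i] += eta_d * (F_d - w[i]);
        dwell_d(i, lap) += dt;
      } else if (eta_pre > 0.0) {
        w[i] += eta_pre * (F_pre - w[i]);
      }
      if (rec_of[i] >= 0) {
        ca_rec(rec_of[i], s) = ca;
        w_rec(rec_of[i], s) = w[i];
      }
    }

    // voltage: exact clamp during induction, leaky integration otherwise
    if (plateau[s]) {
      V = V_plateau;
    } else {
      V = V_rest + (V - V_rest) * decay_v + syn_in * syn_scale / C_m;
    }
    voltage[s] = V;
  }

  List rec_spk(n_rec);
  for (int j = 0; j < n_rec; ++j) rec_spk[j] = wrap(rec_spikes[j]);

  return List::create(
    _["voltage"] = voltage,
    _["weights_final"] = NumericVector(w.begin(), w.end()),
    _["w_rec"] = w_rec,
    _["ca_rec"] = ca_rec,
    _["dwell_depressive"] = dwell_d,
    _["dwell_potentiative"] = dwell_p,
    _["spike_count"] = spike_count,
    _["rec_spikes"] = rec_spk,
    _["plateau"] = plateau);
}
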