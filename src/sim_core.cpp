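#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Fixed-step network integrator. Cells are adaptive conductance-based LIF
// units (exponential-Euler membrane update, spike-triggered fast AHP
// conductance w and Ca-gated K conductance). Synapses are event-driven
// Tsodyks-Markram connections delivering peak-normalized exponential
// conductance increments into shared per-cell channels after per-contact
// delays. External drive is a set of independent Poisson processes.
//
// All wiring randomness is drawn in R at build time; the only randomness
// here is the Poisson drive, generated with a private mt19937_64 stream so
// that results are reproducible across platforms.

static inline double exp_draw(std::mt19937_64 &rng) {
  // uniform in (0,1) from the top 53 bits; portable across stdlib versions
  double u = ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  return -std::log(u);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_cells,
              NumericVector c_m, NumericVector g_leak, NumericVector e_leak,
              NumericVector v_thresh, NumericVector v_reset,
              NumericVector refrac, NumericVector w_jump,
              NumericVector tau_w, NumericVector e_k, NumericVector g_kdr_tonic,
              NumericVector ca_jump,
              NumericVector tau_ca, NumericVector g_kca_max,
              NumericVector k_half, NumericVector v0,
              NumericVector chan_tau, NumericVector chan_erev,
              IntegerVector conn_pre, IntegerVector conn_post,
              NumericVector conn_gpeak, NumericVector conn_U,
              NumericVector conn_F, NumericVector conn_D,
              IntegerVector conn_chan_fast, IntegerVector conn_chan_slow,
              NumericVector conn_slow_ratio,
              IntegerVector conn_syn_start, IntegerVector conn_syn_count,
              IntegerVector syn_delay_steps,
              IntegerVector pre_conn_start, IntegerVector pre_conn_count,
              IntegerVector pre_conn_idx,
              IntegerVector drv_post, NumericVector drv_rate,
              NumericVector drv_gpeak, IntegerVector drv_chan_fast,
              IntegerVector drv_chan_slow, NumericVector drv_slow_ratio,
              IntegerVector drv_syn_start, IntegerVector drv_syn_count,
              IntegerVector drv_syn_delay_steps,
              double dt, int n_steps, double seed,
              IntegerVector record_cells, int record_stride) {
  const int K = chan_tau.size();
  const int n_conn = conn_pre.size();
  const int n_drv = drv_post.size();

  std::vector<double> chan_decay(K);
  for (int k = 0; k < K; ++k) chan_decay[k] = std::exp(-dt / chan_tau[k]);

  // per-cell state
  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> W(n_cells, 0.0), Ca(n_cells, 0.0);
  std::vector<double> refrac_until(n_cells, -1e300);
  std::vector<double> w_decay(n_cells), ca_decay(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    w_decay[i] = std::exp(-dt / tau_w[i]);
    ca_decay[i] = std::exp(-dt / tau_ca[i]);
  }
  // conductance channels, cell-major
  std::vector<double> G((size_t)n_cells * K, 0.0);

  // TM state per connection
  std::vector<double> tm_u(n_conn, 0.0), tm_R(n_conn, 1.0),
      tm_tlast(n_conn, -1e300);
  std::vector<char> tm_virgin(n_conn, 1);

  // delay ring buffer
  int max_delay = 1;
  for (int i = 0; i < syn_delay_steps.size(); ++i)
    if (syn_delay_steps[i] > max_delay) max_delay = syn_delay_steps[i];
  for (int i = 0; i < drv_syn_delay_steps.size(); ++i)
    if (drv_syn_delay_steps[i] > max_delay) max_delay = drv_syn_delay_steps[i];
  int ring_n = 1;
  while (ring_n < max_delay + 2) ring_n <<= 1;
  const int ring_mask = ring_n - 1;
  std::vector<std::vector<std::pair<int, double>>> ring(ring_n);

  // Poisson drive next-event times
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<double> drv_next(n_drv);
  const double t_end = n_steps * dt;
  for (int d = 0; d < n_drv; ++d) {
    double rate_ms = drv_rate[d] / 1000.0;
    drv_next[d] = (rate_ms > 0) ? exp_draw(rng) / rate_ms : 2 * t_end + 1.0;
  }

  std::vector<int> sp_cell;
  std::vector<double> sp_time;
  const int n_rec = record_cells.size();
  int n_rec_rows = (n_rec > 0) ? (n_steps / record_stride + 1) : 0;
  NumericMatrix vrec(n_rec_rows, n_rec);
  int rec_row = 0;

  std::vector<int> spiked_now;
  spiked_now.reserve(64);

  for (int s = 0; s < n_steps; ++s) {
    const double t0 = s * dt, t1 = (s + 1) * dt;

    // schedule Poisson drive events falling in (t0, t1]
    for (int d = 0; d < n_drv; ++d) {
      while (drv_next[d] <= t1) {
        int base = drv_syn_start[d];
        for (int j = 0; j < drv_syn_count[d]; ++j) {
          int del = drv_syn_delay_steps[base + j];
          int slot = (s + del) & ring_mask;
          ring[slot].push_back({drv_post[d] * K + drv_chan_fast[d],
                                drv_gpeak[d]});
          if (drv_chan_slow[d] >= 0 && drv_slow_ratio[d] != 0)
            ring[slot].push_back({drv_post[d] * K + drv_chan_slow[d],
                                  drv_gpeak[d] * drv_slow_ratio[d]});
        }
        double rate_ms = drv_rate[d] / 1000.0;
        drv_next[d] += exp_draw(rng) / rate_ms;
      }
    }

    // decay channels, then deliver events due this step
    for (size_t i = 0; i < G.size(); ++i) G[i] *= chan_decay[i % K];
    {
      auto &due = ring[s & ring_mask];
      for (auto &ev : due) G[ev.first] += ev.second;
      due.clear();
    }

    // membrane + adaptation update
    spiked_now.clear();
    for (int i = 0; i < n_cells; ++i) {
      W[i] *= w_decay[i];
      Ca[i] *= ca_decay[i];
      double g_ad = W[i] + g_kdr_tonic[i] +
                    g_kca_max[i] * Ca[i] / (Ca[i] + k_half[i]);
      double gt = g_leak[i] + g_ad;
      double num = g_leak[i] * e_leak[i] + g_ad * e_k[i];
      const double *gi = &G[(size_t)i * K];
      for (int k = 0; k < K; ++k) {
        gt += gi[k];
        num += gi[k] * chan_erev[k];
      }
      double vinf = num / gt;
      double v = vinf + (V[i] - vinf) * std::exp(-gt * dt / c_m[i]);
      if (t1 < refrac_until[i]) {
        V[i] = v_reset[i];
        continue;
      }
      if (v >= v_thresh[i]) {
        sp_cell.push_back(i);
        sp_time.push_back(t1);
        V[i] = v_reset[i];
        W[i] += w_jump[i];
        Ca[i] += ca_jump[i];
        refrac_until[i] = t1 + refrac[i];
        spiked_now.push_back(i);
      } else {
        if (!std::isfinite(v))
          stop("non-finite membrane potential in cell %d at t = %f ms", i + 1,
               t1);
        V[i] = v;
      }
    }

    // propagate spikes through TM connections
    for (int ci : spiked_now) {
      int c0 = pre_conn_start[ci];
      for (int j = 0; j < pre_conn_count[ci]; ++j) {
        int c = pre_conn_idx[c0 + j];
        double u, R;
        if (tm_virgin[c]) {
          u = conn_U[c];
          R = 1.0;
          tm_virgin[c] = 0;
        } else {
          double del_t = t1 - tm_tlast[c];
          u = (conn_F[c] > 0) ? tm_u[c] * std::exp(-del_t / conn_F[c]) : 0.0;
          u = u + conn_U[c] * (1.0 - u);
          if (conn_F[c] == 0) u = conn_U[c];
          R = (conn_D[c] > 0)
                  ? 1.0 - (1.0 - tm_R[c]) * std::exp(-del_t / conn_D[c])
                  : 1.0;
        }
        double release = u * R;
        tm_u[c] = u;
        tm_R[c] = R * (1.0 - u);
        tm_tlast[c] = t1;
        double amp = conn_gpeak[c] * release / conn_U[c];
        int post = conn_post[c];
        int s0 = conn_syn_start[c];
        for (int m = 0; m < conn_syn_count[c]; ++m) {
          int slot = (s + syn_delay_steps[s0 + m]) & ring_mask;
          ring[slot].push_back({post * K + conn_chan_fast[c], amp});
          if (conn_chan_slow[c] >= 0 && conn_slow_ratio[c] != 0)
            ring[slot].push_back(
                {post * K + conn_chan_slow[c], amp * conn_slow_ratio[c]});
        }
      }
    }

    if (n_rec > 0 && (s % record_stride) == 0) {
      for (int r = 0; r < n_rec; ++r) vrec(rec_row, r) = V[record_cells[r]];
      ++rec_row;
    }
  }

  return List::create(_["cell"] = wrap(sp_cell), _["time"] = wrap(sp_time),
                      _["v"] = vrec);
}

// Brute-force oracle: integrates the TM differential equations
//   du/dt = -u/F   (F = 0: u clamped to U between events)
//   dR/dt = (1 - R)/D   (D = 0: R clamped to 1)
// with classical RK4 at a fine step, applying at each spike the jump
// u -> u + U(1-u), recording release u*R, then R -> R(1-u). Deliberately a
// different algorithm from the event-driven closed-form recursion so it can
// serve as an independent check of it.
static inline double rk4_decay(double x, double target, double tau,
                               double h) {
  // dx/dt = (target - x)/tau
  double k1 = (target - x) / tau;
  double k2 = (target - (x + 0.5 * h * k1)) / tau;
  double k3 = (target - (x + 0.5 * h * k2)) / tau;
  double k4 = (target - (x + h * k3)) / tau;
  return x + h / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
}

// [[Rcpp::export(name = ".tm_ode_oracle")]]
NumericVector tm_ode_oracle(NumericVector spike_times, double U, double F,
                            double D, double dt) {
  int n = spike_times.size();
  NumericVector rel(n);
  double u = 0.0, R = 1.0, t = 0.0;
  for (int i = 0; i < n; ++i) {
    double ts = spike_times[i];
    while (t + dt <= ts) {
      u = (F > 0) ? rk4_decay(u, 0.0, F, dt) : 0.0;
      R = (D > 0) ? rk4_decay(R, 1.0, D, dt) : 1.0;
      t += dt;
    }
    double rem = ts - t;
    if (rem > 0) {
      u = (F > 0) ? rk4_decay(u, 0.0, F, rem) : 0.0;
      R = (D > 0) ? rk4_decay(R, 1.0, D, rem) : 1.0;
      t = ts;
    }
    u = u + U * (1.0 - u);
    if (F == 0) u = U;
    rel[i] = u * R;
    R = R * (1.0 - u);
  }
  return rel;
}
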