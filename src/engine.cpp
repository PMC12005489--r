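#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time world stepper for non-interacting sperm agents.
//
// RNG contract (shared with the pure-R reference engine): R's global RNG,
// consumed per step in fixed agent-index order:
//   1. if the agent's calcium gate is open: one unif_rand() for the
//      Markov transition draw;
//   2. one norm_rand() for the angular noise, then one norm_rand() for
//      the radial noise;
//   3. if the proposed move is blocked: one unif_rand() for the uniform
//      half-circle reorientation, then one norm_rand() for the
//      class-specific angular perturbation.
//
// stop_rule: 1 = first_contact, 2 = cumulative_contact, 3 = fixed_duration.

static inline int cum_lookup(const double* row, double u) {
  double c = 0.0;
  for (int j = 0; j < 5; ++j) {
    c += row[j];
    if (u <= c) return j;
  }
  return 4;
}

// [[Rcpp::export]]
List run_engine_cpp(LogicalMatrix barrier, double cell_size,
                    IntegerVector egg_cell,      // 1-based (col, row)
                    NumericVector x0, NumericVector y0,
                    NumericVector heading0, IntegerVector state0, // 1-based
                    NumericVector omega_hz,      // length 0 => fixed-class mode
                    NumericMatrix trans,         // 5x5 row-stochastic
                    double ca_threshold,
                    NumericMatrix params,        // 5x4: v, sigma_r, omega_deg, sigma_theta_deg
                    double tau,
                    int stop_rule, double contact_threshold_s,
                    int duration_steps, double max_steps_d,
                    bool record_traj, bool record_occupancy) {
  RNGScope scope;
  const int nx = barrier.nrow(), ny = barrier.ncol();
  const int n = x0.size();
  const int egx = egg_cell[0] - 1, egy = egg_cell[1] - 1;
  const bool markov = omega_hz.size() > 0;
  const double deg2rad = M_PI / 180.0;
  const double sqrt_tau = std::sqrt(tau);
  const long long max_steps = (long long)max_steps_d;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(heading0.begin(), heading0.end());
  std::vector<int> st(n);
  for (int i = 0; i < n; ++i) st[i] = state0[i] - 1;

  // pre-extract transition rows and class parameters
  double P[5][5];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) P[i][j] = trans(i, j);
  double V[5], SR[5], OM[5], STH[5];
  for (int i = 0; i < 5; ++i) {
    V[i] = params(i, 0);
    SR[i] = params(i, 1);
    OM[i] = params(i, 2) * deg2rad;
    STH[i] = params(i, 3) * deg2rad;
  }

  LogicalMatrix visited(nx, ny);
  long long n_visited = 0;
  std::vector<double> contact(n, 0.0);
  double total_contact = 0.0;
  long long first_contact_step = -1;
  long long visited_at_first = -1;

  // initial bookkeeping: mark starting cells, detect time-zero egg contact
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(x[i] / cell_size);
    int cy = (int)std::floor(y[i] / cell_size);
    if (cx < 0 || cx >= nx || cy < 0 || cy >= ny || barrier(cx, cy))
      stop("agent initialised outside the corridor");
    if (!visited(cx, cy)) { visited(cx, cy) = true; ++n_visited; }
    if (cx == egx && cy == egy && first_contact_step < 0) {
      first_contact_step = 0;
      visited_at_first = n_visited;
    }
  }

  std::vector<double> traj_x, traj_y;
  std::vector<int> occ;
  if (record_traj) {
    traj_x.insert(traj_x.end(), x.begin(), x.end());
    traj_y.insert(traj_y.end(), y.begin(), y.end());
  }
  if (record_occupancy) {
    int counts[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) counts[st[i]]++;
    for (int j = 0; j < 5; ++j) occ.push_back(counts[j]);
  }

  long long k = 0;
  int end_reason = 0; // 1 first_contact, 2 cumulative, 3 duration, 4 timeout
  if (stop_rule == 1 && first_contact_step == 0) end_reason = 1;

  while (end_reason == 0) {
    if (k >= max_steps) { end_reason = 4; break; }
    double s = (k % 2 == 0) ? 1.0 : -1.0;
    double t_now = (double)(k + 1) * tau;
    for (int i = 0; i < n; ++i) {
      if (markov && omega_hz[i] > 0) {
        double ca = 0.5 * (1.0 - std::cos(2.0 * M_PI * omega_hz[i] * t_now));
        if (ca > ca_threshold) {
          double u = unif_rand();
          st[i] = cum_lookup(P[st[i]], u);
        }
      }
      int cls = st[i];
      double eta_th = norm_rand();
      th[i] += s * OM[cls] + STH[cls] * eta_th;
      double eta_r = norm_rand();
      double step_len = V[cls] * tau + SR[cls] * sqrt_tau * eta_r;
      double px = x[i] + step_len * std::cos(th[i]);
      double py = y[i] + step_len * std::sin(th[i]);
      int pcx = (int)std::floor(px / cell_size);
      int pcy = (int)std::floor(py / cell_size);
      bool blocked = (pcx < 0 || pcx >= nx || pcy < 0 || pcy >= ny ||
                      barrier(pcx, pcy));
      if (blocked) {
        int ccx = (int)std::floor(x[i] / cell_size);
        int ccy = (int)std::floor(y[i] / cell_size);
        double normal = std::atan2((double)(ccy - pcy), (double)(ccx - pcx));
        double u2 = unif_rand();
        double eta_p = norm_rand();
        th[i] = normal + M_PI * (u2 - 0.5) + STH[cls] * eta_p;
      } else {
        x[i] = px; y[i] = py;
        if (!visited(pcx, pcy)) { visited(pcx, pcy) = true; ++n_visited; }
      }
      int cx = (int)std::floor(x[i] / cell_size);
      int cy = (int)std::floor(y[i] / cell_size);
      if (cx == egx && cy == egy) {
        contact[i] += tau;
        total_contact += tau;
        if (first_contact_step < 0) {
          first_contact_step = k + 1;
          visited_at_first = n_visited;
        }
      }
    }
    ++k;
    if (record_traj) {
      traj_x.insert(traj_x.end(), x.begin(), x.end());
      traj_y.insert(traj_y.end(), y.begin(), y.end());
    }
    if (record_occupancy) {
      int counts[5] = {0, 0, 0, 0, 0};
      for (int i = 0; i < n; ++i) counts[st[i]]++;
      for (int j = 0; j < 5; ++j) occ.push_back(counts[j]);
    }
    if (stop_rule == 1 && first_contact_step >= 0) end_reason = 1;
    else if (stop_rule == 2 && total_contact >= contact_threshold_s - 1e-12)
      end_reason = 2;
    else if (stop_rule == 3 && k >= duration_steps) end_reason = 3;
  }

  List out = List::create(
    _["end_reason"] = end_reason,
    _["n_steps"] = (double)k,
    _["first_contact_step"] = (double)first_contact_step,
    _["visited_at_first_contact"] = (double)visited_at_first,
    _["contact_time_s"] = NumericVector(contact.begin(), contact.end()),
    _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()),
    _["heading"] = NumericVector(th.begin(), th.end()),
    _["state"] = [&]{ IntegerVector v(n); for (int i = 0; i < n; ++i) v[i] = st[i] + 1; return v; }(),
    _["visited"] = visited,
    _["n_visited"] = (double)n_visited);
  if (record_traj) {
    int m = (int)(traj_x.size() / n);
    NumericMatrix tx(n, m), ty(n, m);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) {
        tx(i, j) = traj_x[(size_t)j * n + i];
        ty(i, j) = traj_y[(size_t)j * n + i];
      }
    out["traj_x"] = tx;
    out["traj_y"] = ty;
  }
  if (record_occupancy) {
    int m = (int)(occ.size() / 5);
    NumericMatrix oc(m, 5);
    for (int j = 0; j < m; ++j)
      for (int c = 0; c < 5; ++c) oc(j, c) = occ[(size_t)j * 5 + c] / (double)n;
    out["occupancy"] = oc;
  }
  return out;
}
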