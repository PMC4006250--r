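// Event loops for the direct-method SSA and the rejection-method DSSA.
// All randomness comes from R's RNG (unif_rand / exp_rand), so set.seed()
// in R governs every run.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// propensity types: 0 = mass action (falling factorials on reactant
// stoichiometries), 1 = saturating autocatalytic a = w*V*(phi x)^q/(1+(phi x)^h)
static double propensity(int type, double rate, const NumericVector& par,
                         const IntegerMatrix& react, int j,
                         const std::vector<int>& x) {
  if (type == 0) {
    double a = rate;
    for (int s = 0; s < react.nrow(); ++s) {
      int k = react(s, j);
      for (int q = 0; q < k; ++q) a *= (x[s] - q);
      if (a <= 0.0) return 0.0;
    }
    return a;
  }
  // saturating: par = (V, phi, q, h, species_index, weight)
  int sidx = (int) par[4];
  double xv = x[sidx];
  int need = 0;
  for (int s = 0; s < react.nrow(); ++s) if (react(s, j) > 0 && s == sidx) need = react(s, j);
  if (xv < need) return 0.0;
  double px = par[1] * xv;
  return par[5] * par[0] * std::pow(px, par[2]) / (1.0 + std::pow(px, par[3]));
}

// ---- delay sampling --------------------------------------------------------
// spec: list(type, ...) type 0 stage_rates (rates), 1 residue (terms 4 cols),
// 2 tabulated (time, cdf)
static double residue_cdf_c(const NumericMatrix& tm, double t) {
  double s = 0.0;
  for (int r = 0; r < tm.nrow(); ++r) {
    double a = tm(r, 0), b = tm(r, 1), A = tm(r, 2), B = tm(r, 3);
    s += std::exp(a * t) * (A * std::cos(b * t) - B * std::sin(b * t));
  }
  double F = 1.0 - s;
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

static double sample_delay_c(const List& spec) {
  int type = as<int>(spec["type"]);
  if (type == 0) {
    NumericVector rates = spec["rates"];
    double t = 0.0;
    for (int k = 0; k < rates.size(); ++k) t += exp_rand() / rates[k];
    return t;
  }
  if (type == 1) {
    NumericMatrix tm = spec["terms"];
    double scale = as<double>(spec["scale"]);
    double u = unif_rand();
    double lo = 0.0, hi = scale;
    int guard = 0;
    while (residue_cdf_c(tm, hi) < u && guard++ < 400) hi *= 2.0;
    for (int i = 0; i < 100; ++i) {
      double mid = 0.5 * (lo + hi);
      if (residue_cdf_c(tm, mid) < u) lo = mid; else hi = mid;
    }
    return 0.5 * (lo + hi);
  }
  NumericVector tt = spec["time"], FF = spec["cdf"];
  double u = unif_rand();
  int n = tt.size();
  if (u >= FF[n - 1]) return tt[n - 1];
  // binary search for the bracketing segment
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (FF[mid] < u) lo = mid; else hi = mid;
  }
  double dF = FF[hi] - FF[lo];
  if (dF <= 0.0) return tt[lo];
  return tt[lo] + (u - FF[lo]) / dF * (tt[hi] - tt[lo]);
}

struct Pending {
  double time;
  int inc_col;     // column of the increment matrix
  long seq;        // FIFO within exact ties
  bool operator>(const Pending& o) const {
    if (time != o.time) return time > o.time;
    return seq > o.seq;
  }
};

// record grid states with time strictly below t_next
static void record_until(IntegerMatrix& out, const NumericVector& grid,
                         int& g, double t_next, const std::vector<int>& x) {
  while (g < grid.size() && grid[g] < t_next) {
    for (size_t s = 0; s < x.size(); ++s) out(s, g) = x[s];
    ++g;
  }
}

// [[Rcpp::export]]
List ssa_core(IntegerVector x0, double t_end,
              IntegerMatrix react, IntegerMatrix change,
              NumericVector rates, IntegerVector prop_type, List prop_par,
              NumericVector grid, bool record_events,
              int max_events = 50000000) {
  int nsp = x0.size(), nr = rates.size();
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix gridstate(nsp, grid.size());
  std::vector<double> ev_t;
  std::vector<int> ev_x;
  double t = 0.0;
  int g = 0;
  std::vector<double> a(nr);
  if (record_events) {
    ev_t.push_back(0.0);
    for (int s = 0; s < nsp; ++s) ev_x.push_back(x[s]);
  }
  long n_events = 0;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity(prop_type[j], rates[j], prop_par[j], react, j, x);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;
    double t_next = t + exp_rand() / a0;
    if (t_next > t_end) break;
    record_until(gridstate, grid, g, t_next, x);
    t = t_next;
    double u = unif_rand() * a0;
    int j = 0;
    double c = a[0];
    while (u > c && j < nr - 1) c += a[++j];
    for (int s = 0; s < nsp; ++s) x[s] += change(s, j);
    if (record_events) {
      ev_t.push_back(t);
      for (int s = 0; s < nsp; ++s) ev_x.push_back(x[s]);
    }
    if (++n_events > max_events) stop("event budget exceeded");
  }
  record_until(gridstate, grid, g, R_PosInf, x);
  List out = List::create(_["grid_state"] = gridstate,
                          _["final"] = IntegerVector(x.begin(), x.end()));
  if (record_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    IntegerMatrix em(nsp, ev_t.size());
    for (size_t i = 0; i < ev_t.size(); ++i)
      for (int s = 0; s < nsp; ++s) em(s, i) = ev_x[i * nsp + s];
    out["event_states"] = em;
  }
  return out;
}

// Rejection DSSA: delayed reactions consume reactants at firing time and
// enqueue their products; a queued completion occurring before the tentative
// next firing preempts (rejects) it and the waiting time is redrawn, which
// is exact because exponential waiting times are memoryless.
// [[Rcpp::export]]
List dssa_core(IntegerVector x0, double t_end,
               IntegerMatrix react, IntegerMatrix change,
               NumericVector rates, IntegerVector prop_type, List prop_par,
               LogicalVector is_delayed, IntegerVector inc_col,
               IntegerMatrix increments, List delay_specs,
               NumericVector hist_times, IntegerVector hist_cols,
               NumericVector grid, bool record_events,
               int max_events = 50000000) {
  int nsp = x0.size(), nr = rates.size();
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix gridstate(nsp, grid.size());
  std::vector<double> ev_t;
  std::vector<int> ev_x;
  std::priority_queue<Pending, std::vector<Pending>, std::greater<Pending> > q;
  long seq = 0;
  for (int i = 0; i < hist_times.size(); ++i)
    q.push(Pending{hist_times[i], hist_cols[i], seq++});
  double t = 0.0;
  int g = 0;
  std::vector<double> a(nr);
  if (record_events) {
    ev_t.push_back(0.0);
    for (int s = 0; s < nsp; ++s) ev_x.push_back(x[s]);
  }
  long n_events = 0;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity(prop_type[j], rates[j], prop_par[j], react, j, x);
      a0 += a[j];
    }
    double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    if (!q.empty() && q.top().time <= t_next) {      // completion preempts
      Pending p = q.top();
      if (p.time > t_end) break;
      q.pop();
      record_until(gridstate, grid, g, p.time, x);
      t = p.time;
      if (p.inc_col >= 0)
        for (int s = 0; s < nsp; ++s) x[s] += increments(s, p.inc_col);
      if (record_events) {
        ev_t.push_back(t);
        for (int s = 0; s < nsp; ++s) ev_x.push_back(x[s]);
      }
      if (++n_events > max_events) stop("event budget exceeded");
      continue;
    }
    if (t_next > t_end) break;
    record_until(gridstate, grid, g, t_next, x);
    t = t_next;
    double u = unif_rand() * a0;
    int j = 0;
    double c = a[0];
    while (u > c && j < nr - 1) c += a[++j];
    if (is_delayed[j]) {
      for (int s = 0; s < nsp; ++s) x[s] -= react(s, j);
      if (inc_col[j] >= 0) {
        double tau = sample_delay_c(delay_specs[j]);
        q.push(Pending{t + tau, inc_col[j], seq++});
      }
    } else {
      for (int s = 0; s < nsp; ++s) x[s] += change(s, j);
    }
    if (record_events) {
      ev_t.push_back(t);
      for (int s = 0; s < nsp; ++s) ev_x.push_back(x[s]);
    }
    if (++n_events > max_events) stop("event budget exceeded");
  }
  record_until(gridstate, grid, g, R_PosInf, x);
  List out = List::create(_["grid_state"] = gridstate,
                          _["final"] = IntegerVector(x.begin(), x.end()));
  if (record_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    IntegerMatrix em(nsp, ev_t.size());
    for (size_t i = 0; i < ev_t.size(); ++i)
      for (int s = 0; s < nsp; ++s) em(s, i) = ev_x[i * nsp + s];
    out["event_states"] = em;
  }
  return out;
}
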