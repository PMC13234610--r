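#include <Rcpp.h>
using namespace Rcpp;

// Greedy reinsertion sweep for the linear z-score sequence model.
//
// One sweep over the events in `order`: each event is removed and
// re-inserted at the valid position (within-region threshold order
// preserved) that maximizes the weighted marginal log-likelihood
// sum_j w_j log P(x_j | S). Ties keep the earliest position; a move is
// made only on strict improvement, so the objective never decreases.

namespace {

struct Problem {
  int n, B, N;
  std::vector<double> Zs;     // n x B, column-major, scaled by 1/sigma
  std::vector<double> z2;     // rowSums(Zs^2)
  double cnst;                // Gaussian normalising constant
  std::vector<double> w;
  std::vector<int> ev_region; // 0-based region per event
  std::vector<std::vector<int> > region_events;   // event ids per region,
                                                  // ascending threshold
  std::vector<std::vector<double> > thresholds;   // per region
  std::vector<double> zmax;
  std::vector<double> sigma;
};

// Piecewise-linear trajectories for all regions at stages 0..N,
// scaled by 1/sigma; G is B x (N+1), column-major.
void trajectories(const Problem& P, const std::vector<int>& pos,
                  std::vector<double>& G) {
  for (int i = 0; i < P.B; ++i) {
    const std::vector<int>& ids = P.region_events[i];
    int R = ids.size();
    std::vector<double> kx(R + 2), ky(R + 2);
    kx[0] = 0.0; ky[0] = 0.0;
    for (int r = 0; r < R; ++r) {
      kx[r + 1] = pos[ids[r]];
      ky[r + 1] = P.thresholds[i][r];
    }
    int K = R + 1;                 // knots so far: (0,0) + R events
    if (kx[R] < P.N) {             // ceiling segment up to (N, zmax)
      kx[R + 1] = P.N; ky[R + 1] = P.zmax[i]; K = R + 2;
    }
    int seg = 0;
    for (int k = 0; k <= P.N; ++k) {
      double x = k;
      while (seg < K - 2 && x > kx[seg + 1]) ++seg;
      double g = (x <= kx[seg]) ? ky[seg]
        : (x >= kx[seg + 1]) ? ky[seg + 1]
        : ky[seg] + (x - kx[seg]) * (ky[seg + 1] - ky[seg]) /
            (kx[seg + 1] - kx[seg]);
      G[i + (size_t)P.B * k] = g / P.sigma[i];
    }
  }
}

double objective(const Problem& P, const std::vector<int>& pos,
                 std::vector<double>& G, std::vector<double>& ll_row) {
  trajectories(P, pos, G);
  int K = P.N + 1;
  std::vector<double> g2(K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < P.B; ++i) {
      double v = G[i + (size_t)P.B * k];
      s += v * v;
    }
    g2[k] = s;
  }
  double lpk = std::log((double)K);
  double obj = 0.0;
  for (int j = 0; j < P.n; ++j) {
    if (P.w[j] == 0.0) continue;
    double mx = -1e300;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int i = 0; i < P.B; ++i)
        acc += P.Zs[j + (size_t)P.n * i] * G[i + (size_t)P.B * k];
      double ll = P.cnst - 0.5 * (P.z2[j] + g2[k] - 2.0 * acc);
      ll_row[k] = ll;
      if (ll > mx) mx = ll;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(ll_row[k] - mx);
    obj += P.w[j] * (mx + std::log(s) - lpk);
  }
  return obj;
}

} // namespace

// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(NumericMatrix Z, NumericVector w, NumericVector sigma,
               IntegerVector S, IntegerVector order,
               IntegerVector event_region, IntegerVector event_thr,
               List thresholds, NumericVector zmax) {
  Problem P;
  P.n = Z.nrow(); P.B = Z.ncol(); P.N = S.size();
  P.Zs.resize((size_t)P.n * P.B);
  P.z2.assign(P.n, 0.0);
  P.sigma.assign(sigma.begin(), sigma.end());
  double logdet = 0.0;
  for (int i = 0; i < P.B; ++i) logdet += std::log(P.sigma[i]);
  P.cnst = -0.5 * P.B * std::log(2.0 * M_PI) - logdet;
  for (int i = 0; i < P.B; ++i)
    for (int j = 0; j < P.n; ++j) {
      double v = Z(j, i) / P.sigma[i];
      P.Zs[j + (size_t)P.n * i] = v;
      P.z2[j] += v * v;
    }
  P.w.assign(w.begin(), w.end());
  P.ev_region.resize(P.N);
  for (int e = 0; e < P.N; ++e) P.ev_region[e] = event_region[e] - 1;
  P.region_events.resize(P.B);
  for (int e = 0; e < P.N; ++e)
    P.region_events[P.ev_region[e]].push_back(e);
  // canonical event order is region-major, ascending threshold, so the
  // push_back order above is already ascending in threshold
  P.thresholds.resize(P.B);
  for (int i = 0; i < P.B; ++i) {
    NumericVector th = thresholds[i];
    P.thresholds[i].assign(th.begin(), th.end());
  }
  P.zmax.assign(zmax.begin(), zmax.end());

  std::vector<int> seq(P.N);       // seq[pos] = event (0-based)
  for (int p = 0; p < P.N; ++p) seq[p] = S[p] - 1;
  std::vector<int> pos(P.N);       // pos[event] = 1-based position
  for (int p = 0; p < P.N; ++p) pos[seq[p]] = p + 1;

  std::vector<double> G((size_t)P.B * (P.N + 1));
  std::vector<double> ll_row(P.N + 1);
  double obj = objective(P, pos, G, ll_row);
  bool improved = false;

  for (int oi = 0; oi < order.size(); ++oi) {
    int e = order[oi] - 1;
    int cur = pos[e];              // 1-based
    // valid position bounds from within-region neighbours
    int lo = 1, hi = P.N;
    const std::vector<int>& ids = P.region_events[P.ev_region[e]];
    for (size_t r = 0; r < ids.size(); ++r) {
      if (ids[r] == e) continue;
      int q = pos[ids[r]];
      int q_rm = (q > cur) ? q - 1 : q; // position after removing e
      if (event_thr[ids[r]] < event_thr[e]) { if (q_rm + 1 > lo) lo = q_rm + 1; }
      else { if (q_rm < hi) hi = q_rm; }
    }
    if (lo >= hi) continue;
    int best_p = cur;
    double best_obj = obj;
    std::vector<int> cand_pos(P.N);
    for (int p = lo; p <= hi; ++p) {
      if (p == cur) continue;
      // positions after removing e and inserting at p
      for (int f = 0; f < P.N; ++f) {
        int q = pos[f];
        if (f == e) { cand_pos[f] = p; continue; }
        int q_rm = (q > cur) ? q - 1 : q;
        cand_pos[f] = (q_rm >= p) ? q_rm + 1 : q_rm;
      }
      double o = objective(P, cand_pos, G, ll_row);
      if (o > best_obj + 1e-12) { best_obj = o; best_p = p; }
    }
    if (best_p != cur) {
      for (int f = 0; f < P.N; ++f) {
        int q = pos[f];
        if (f == e) { pos[f] = best_p; continue; }
        int q_rm = (q > cur) ? q - 1 : q;
        pos[f] = (q_rm >= best_p) ? q_rm + 1 : q_rm;
      }
      obj = best_obj;
      improved = true;
    }
  }
  IntegerVector S_out(P.N);
  for (int f = 0; f < P.N; ++f) S_out[pos[f] - 1] = f + 1;
  return List::create(_["sequence"] = S_out, _["objective"] = obj,
                      _["improved"] = improved);
}
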