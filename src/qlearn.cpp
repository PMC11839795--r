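// Episodic epsilon-greedy tabular Q-learning over a voxel adjacency graph.
// Penalty-minimizing form: greedy = argmin over finite Q, best_next = min.
// Moves are indexed in lexicographic offset order so argmin ties resolve to
// the lexicographically smallest neighbor, matching the R-side extractor.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy descent from `entry`; returns true iff a target voxel is reached
// without revisiting a voxel or hitting a dead end. On success `cost`
// accumulates step_cost * move multiplier + destination risk.
static bool greedy_path(const NumericMatrix& q, const LogicalMatrix& valid,
                        const IntegerMatrix& nbr, const NumericVector& risk,
                        const NumericVector& step_mult, double step_cost,
                        const LogicalVector& is_target, int entry,
                        std::vector<int>& path, std::vector<char>& seen,
                        double& cost) {
  std::fill(seen.begin(), seen.end(), 0);
  path.clear();
  cost = 0.0;
  const int n = q.nrow(), m = q.ncol();
  int u = entry;
  path.push_back(u);
  seen[u - 1] = 1;
  if (is_target[u - 1]) return true;
  for (int step = 0; step < n; ++step) {
    int best = -1;
    double bq = R_PosInf;
    for (int mm = 0; mm < m; ++mm) {
      if (valid(u - 1, mm) && q(u - 1, mm) < bq) {
        bq = q(u - 1, mm);
        best = mm;
      }
    }
    if (best < 0) return false;
    int v = nbr(u - 1, best);
    if (seen[v - 1]) return false;
    cost += step_cost * step_mult[best] + risk[v - 1];
    path.push_back(v);
    seen[v - 1] = 1;
    u = v;
    if (is_target[u - 1]) return true;
  }
  return false;
}

// [[Rcpp::export]]
List train_q_cpp(NumericMatrix q_in, LogicalMatrix valid, IntegerMatrix nbr,
                 NumericVector risk, LogicalVector is_target, int entry,
                 double alpha, double gamma, double eps_start, double eps_min,
                 double eps_decay, int episodes_max, int stable_episodes,
                 double step_cost, NumericVector step_mult, bool goal_terminal,
                 int step_cap) {
  NumericMatrix q = clone(q_in);
  const int n = q.nrow(), m = q.ncol();
  double eps = eps_start;
  std::vector<int> path, prev;
  std::vector<char> seen(n);
  std::vector<int> finite_moves(m);
  NumericVector greedy_costs(episodes_max, NA_REAL);
  bool converged = false;
  int stable = 0, episodes = 0, completed = 0;

  for (int ep = 0; ep < episodes_max; ++ep) {
    int s = entry;
    for (int step = 0; step < step_cap; ++step) {
      int k = 0;
      for (int mm = 0; mm < m; ++mm)
        if (valid(s - 1, mm)) finite_moves[k++] = mm;
      if (k == 0) break;  // dead end (isolated voxel)
      int mv;
      if (unif_rand() < eps) {
        int r = (int)(unif_rand() * k);
        if (r >= k) r = k - 1;
        mv = finite_moves[r];
      } else {
        mv = finite_moves[0];
        double bq = q(s - 1, mv);
        for (int ii = 1; ii < k; ++ii) {
          double v = q(s - 1, finite_moves[ii]);
          if (v < bq) { bq = v; mv = finite_moves[ii]; }
        }
      }
      const int d = nbr(s - 1, mv);
      const double R = step_cost * step_mult[mv] + risk[d - 1];
      double best_next = 0.0;
      if (!(goal_terminal && is_target[d - 1])) {
        double b = R_PosInf;
        for (int mm = 0; mm < m; ++mm)
          if (valid(d - 1, mm) && q(d - 1, mm) < b) b = q(d - 1, mm);
        if (R_finite(b)) best_next = b;
      }
      q(s - 1, mv) += alpha * (R + gamma * best_next - q(s - 1, mv));
      s = d;
      if (is_target[s - 1]) { ++completed; break; }
    }
    episodes = ep + 1;
    eps = std::max(eps_min, eps * eps_decay);
    double gcost;
    bool reached = greedy_path(q, valid, nbr, risk, step_mult, step_cost,
                               is_target, entry, path, seen, gcost);
    if (reached) greedy_costs[ep] = gcost;
    if (reached && path == prev) {
      ++stable;
    } else {
      stable = reached ? 1 : 0;
      prev = path;
    }
    if (stable >= stable_episodes) { converged = true; break; }
  }
  return List::create(
      _["q"] = q, _["episodes_run"] = episodes, _["converged"] = converged,
      _["completed_episodes"] = completed,
      _["greedy_costs"] = greedy_costs[Rcpp::Range(0, episodes - 1)]);
}
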