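#include <Rcpp.h>
using namespace Rcpp;

// Synchronous discrete-time SI epidemic on a weighted network.
//
// W: N x N symmetric weight matrix, entries in [0,1]; seed0: 0-based seed
// indices; beta: per-link infection probability scale; T: integration
// horizon in steps; n_runs: Monte-Carlo realizations. Uses R's RNG so
// set.seed() on the R side makes runs reproducible.
//
// A susceptible node j becomes infected at step t+1 with probability
// 1 - prod_{i infected at t} (1 - beta * w_ij); the product is maintained
// incrementally in log space, folding in only newly infected nodes.
//
// Returns counts, an N x (T+1) integer matrix: counts(i, t) = number of
// runs in which node i first became infected at step t (seed nodes at 0).
// [[Rcpp::export]]
IntegerMatrix si_simulate_cpp(NumericMatrix W, IntegerVector seed0,
                              double beta, int T, int n_runs) {
  const int N = W.nrow();
  IntegerMatrix counts(N, T + 1);
  std::vector<double> logq(N);
  std::vector<bool> inf(N);
  std::vector<int> sus, frontier;
  sus.reserve(N);
  frontier.reserve(N);

  for (int run = 0; run < n_runs; ++run) {
    std::fill(inf.begin(), inf.end(), false);
    std::fill(logq.begin(), logq.end(), 0.0);
    for (int k = 0; k < seed0.size(); ++k) inf[seed0[k]] = true;
    sus.clear();
    for (int j = 0; j < N; ++j)
      if (!inf[j]) sus.push_back(j);
    frontier.assign(seed0.begin(), seed0.end());
    for (int k = 0; k < seed0.size(); ++k) counts(seed0[k], 0)++;

    for (int t = 1; t <= T && !sus.empty(); ++t) {
      for (size_t f = 0; f < frontier.size(); ++f) {
        const int i = frontier[f];
        for (size_t a = 0; a < sus.size(); ++a) {
          const double w = W(i, sus[a]);
          if (w > 0) logq[sus[a]] += std::log1p(-beta * w);
        }
      }
      frontier.clear();
      size_t keep = 0;
      for (size_t a = 0; a < sus.size(); ++a) {
        const int j = sus[a];
        const double p = -std::expm1(logq[j]);  // 1 - exp(logq)
        if (p > 0.0 && unif_rand() < p) {
          counts(j, t)++;
          frontier.push_back(j);
        } else {
          sus[keep++] = j;
        }
      }
      sus.resize(keep);
    }
  }
  return counts;
}

// Slow-propagation (beta -> 0) limit: exactly one susceptible node is
// infected per step, chosen with probability proportional to the total
// weight of its links to already-infected nodes. Nodes left with zero
// infection pressure are unreachable and the run stops there.
//
// Returns step_sum (sum of activation steps over runs, seed nodes 0) and
// reached (number of runs in which the node was ever activated).
// [[Rcpp::export]]
List slow_propagation_cpp(NumericMatrix W, IntegerVector seed0, int n_runs) {
  const int N = W.nrow();
  NumericVector step_sum(N);
  IntegerVector reached(N);
  std::vector<double> press(N);
  std::vector<bool> inf(N);
  std::vector<int> sus;
  sus.reserve(N);

  for (int run = 0; run < n_runs; ++run) {
    std::fill(inf.begin(), inf.end(), false);
    std::fill(press.begin(), press.end(), 0.0);
    for (int k = 0; k < seed0.size(); ++k) inf[seed0[k]] = true;
    sus.clear();
    for (int j = 0; j < N; ++j)
      if (!inf[j]) sus.push_back(j);
    for (size_t a = 0; a < sus.size(); ++a) {
      double s = 0.0;
      for (int k = 0; k < seed0.size(); ++k) s += W(seed0[k], sus[a]);
      press[sus[a]] = s;
    }

    int step = 0;
    while (!sus.empty()) {
      double tot = 0.0;
      for (size_t a = 0; a < sus.size(); ++a) tot += press[sus[a]];
      if (tot <= 0.0) break;  // everything left is disconnected from the front
      double u = unif_rand() * tot;
      size_t pick = sus.size() - 1;
      double acc = 0.0;
      for (size_t a = 0; a < sus.size(); ++a) {
        acc += press[sus[a]];
        if (u < acc) { pick = a; break; }
      }
      const int j = sus[pick];
      ++step;
      step_sum[j] += step;
      reached[j]++;
      sus.erase(sus.begin() + pick);
      for (size_t a = 0; a < sus.size(); ++a) press[sus[a]] += W(j, sus[a]);
    }
  }
  for (int k = 0; k < seed0.size(); ++k) reached[seed0[k]] = n_runs;
  return List::create(_["step_sum"] = step_sum, _["reached"] = reached);
}
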