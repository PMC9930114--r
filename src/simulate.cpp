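#include <Rcpp.h>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Concurrent-growth Mayo-Lewis propagation loop.
//
// All chains are "living" (RDRP): each step picks a living chain uniformly
// at random and appends one monomer drawn with probability proportional to
// pool_j / r(terminal, j), depleting a shared finite pool. A chain with no
// units yet draws from the raw pool fractions. Chains retire when they reach
// their pre-sampled target length; the run stops when `needed` units have
// been consumed, no living chain remains, or the pool is empty.
//
// Uses R's RNG (unif_rand) so set.seed() on the R side makes runs
// bit-reproducible.
//
// [[Rcpp::export]]
List cpp_simulate_batch(NumericVector pool0, NumericMatrix rr,
                        IntegerVector targets, double needed,
                        int n_checkpoints) {
  const int k = pool0.size();
  const int nc = targets.size();
  if (rr.nrow() != k || rr.ncol() != k)
    stop("reactivity matrix does not match pool size");

  std::vector<double> pool(pool0.begin(), pool0.end());
  double pool_total = std::accumulate(pool.begin(), pool.end(), 0.0);
  if (pool_total <= 0) stop("empty initial pool");

  std::vector< std::vector<int> > chains(nc);
  for (int i = 0; i < nc; ++i) chains[i].reserve(targets[i]);

  std::vector<int> living(nc);
  for (int i = 0; i < nc; ++i) living[i] = i;
  int n_living = nc;

  std::vector<double> consumed_by(k, 0.0);
  double consumed = 0.0;

  // pool mole-fraction trajectory, recorded at even consumption intervals
  NumericMatrix traj(n_checkpoints + 1, k);
  for (int j = 0; j < k; ++j) traj(0, j) = pool[j] / pool_total;
  double cp_step = needed / n_checkpoints;
  int next_cp = 1;

  std::vector<double> w(k);

  while (consumed < needed && n_living > 0 && pool_total > 0.5) {
    int li = (int)(unif_rand() * n_living);
    if (li >= n_living) li = n_living - 1;
    int ci = living[li];
    std::vector<int> &ch = chains[ci];

    double wsum = 0.0;
    if (ch.empty()) {
      for (int j = 0; j < k; ++j) { w[j] = pool[j]; wsum += w[j]; }
    } else {
      int t = ch.back();
      for (int j = 0; j < k; ++j) { w[j] = pool[j] / rr(t, j); wsum += w[j]; }
    }
    if (wsum <= 0) break;  // nothing left this radical can add

    double u = unif_rand() * wsum;
    int j = 0;
    double acc = w[0];
    while (j < k - 1 && u > acc) acc += w[++j];
    // guard against selecting a depleted type through float round-off
    if (pool[j] < 0.5) {
      j = -1;
      for (int j2 = 0; j2 < k; ++j2)
        if (pool[j2] >= 0.5 && w[j2] > 0) { j = j2; break; }
      if (j < 0) break;
    }

    ch.push_back(j);
    pool[j] -= 1.0;
    pool_total -= 1.0;
    consumed += 1.0;
    consumed_by[j] += 1.0;

    if ((int)ch.size() >= targets[ci]) {
      living[li] = living[--n_living];
    }

    while (next_cp <= n_checkpoints && consumed >= next_cp * cp_step - 1e-9) {
      for (int j2 = 0; j2 < k; ++j2)
        traj(next_cp, j2) = pool_total > 0.5 ? pool[j2] / pool_total : 0.0;
      ++next_cp;
    }
  }

  List out_chains(nc);
  for (int i = 0; i < nc; ++i) {
    const std::vector<int> &ch = chains[i];
    IntegerVector v(ch.size());
    for (size_t p = 0; p < ch.size(); ++p) v[p] = ch[p] + 1;  // 1-based
    out_chains[i] = v;
  }

  return List::create(
    _["chains"] = out_chains,
    _["consumed"] = NumericVector(consumed_by.begin(), consumed_by.end()),
    _["pool_trajectory"] = traj
  );
}
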