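#include <Rcpp.h>
using namespace Rcpp;

// Forward simulation of the death-Birth process. One RNG stream (R's own,
// so set.seed on the R side makes the whole trial sequence reproducible).
// Each trial: one mutant at a uniform vertex; each step a uniform death
// vertex d, then a parent among d's neighbors with probability proportional
// to fitness * edge weight; absorb at all-mutant or all-resident.
// [[Rcpp::export]]
List simulate_fixation_cpp(NumericMatrix w, double r, int trials,
                           double max_steps) {
  const int N = w.nrow();

  // adjacency lists with cumulative-weight tables for inversion sampling
  std::vector< std::vector<int> > nbr(N);
  std::vector< std::vector<double> > wt(N);
  for (int d = 0; d < N; ++d) {
    for (int j = 0; j < N; ++j) {
      if (w(j, d) > 0.0) {
        nbr[d].push_back(j);
        wt[d].push_back(w(j, d));
      }
    }
    if (nbr[d].empty())
      stop("isolated vertex in simulation (weighted degree 0)");
  }

  int fixed = 0, capped = 0;
  double total_steps = 0.0;
  std::vector<char> mut(N);

  RNGScope scope;
  for (int t = 0; t < trials; ++t) {
    std::fill(mut.begin(), mut.end(), 0);
    int start = (int)(unif_rand() * N);
    if (start == N) start = N - 1;
    mut[start] = 1;
    int count = 1;
    double steps = 0.0;
    bool cap_hit = false;

    while (count > 0 && count < N) {
      if (max_steps > 0 && steps >= max_steps) { cap_hit = true; break; }
      int d = (int)(unif_rand() * N);
      if (d == N) d = N - 1;
      const std::vector<int>& nb = nbr[d];
      const std::vector<double>& nw = wt[d];
      double tot = 0.0;
      for (size_t k = 0; k < nb.size(); ++k)
        tot += (mut[nb[k]] ? r : 1.0) * nw[k];
      double u = unif_rand() * tot;
      double acc = 0.0;
      int parent = nb.back();
      for (size_t k = 0; k < nb.size(); ++k) {
        acc += (mut[nb[k]] ? r : 1.0) * nw[k];
        if (u <= acc) { parent = nb[k]; break; }
      }
      char newtype = mut[parent];
      count += (int)newtype - (int)mut[d];
      mut[d] = newtype;
      steps += 1.0;
    }
    total_steps += steps;
    if (cap_hit) ++capped;
    else if (count == N) ++fixed;
  }

  return List::create(_["fixed"] = fixed, _["capped"] = capped,
                      _["total_steps"] = total_steps);
}
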