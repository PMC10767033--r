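#include <Rcpp.h>
using namespace Rcpp;

// Simulated annealing for a QUBO written as
//   E(x) = sum_i diagQ[i] x_i + (1/2) sum_{i != j} S[i][j] x_i x_j
// where S is the symmetrized off-diagonal coupling matrix (zero diag).
// Single-flip Metropolis, geometric cooling from tInit to tFinal,
// nRestarts independent chains; each restart reports the best state it
// visited.  Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List anneal_qubo_cpp(NumericMatrix S, NumericVector diagQ,
                     int nRestarts, int nSweeps,
                     double tInit, double tFinal) {
  const int d = diagQ.size();
  IntegerMatrix best(nRestarts, d);
  NumericVector bestE(nRestarts);
  const double cool = (nSweeps > 1)
      ? std::pow(tFinal / tInit, 1.0 / (nSweeps - 1)) : 1.0;

  std::vector<int> x(d);
  std::vector<double> field(d);  // field[i] = sum_j S(i,j) x_j

  for (int r = 0; r < nRestarts; ++r) {
    double energy = 0.0;
    for (int i = 0; i < d; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
    for (int i = 0; i < d; ++i) {
      double f = 0.0;
      for (int j = 0; j < d; ++j) f += S(i, j) * x[j];
      field[i] = f;
      if (x[i]) energy += diagQ[i] + 0.5 * f;
    }
    double bE = energy;
    std::vector<int> bx = x;
    double temp = tInit;
    for (int s = 0; s < nSweeps; ++s) {
      for (int i = 0; i < d; ++i) {
        const double dE = (1 - 2 * x[i]) * (diagQ[i] + field[i]);
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / temp)) {
          const int delta = 1 - 2 * x[i];
          x[i] += delta;
          energy += dE;
          for (int j = 0; j < d; ++j) field[j] += delta * S(j, i);
          if (energy < bE) { bE = energy; bx = x; }
        }
      }
      temp *= cool;
    }
    bestE[r] = bE;
    for (int i = 0; i < d; ++i) best(r, i) = bx[i];
  }
  return List::create(_["states"] = best, _["energies"] = bestE);
}
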