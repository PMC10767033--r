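#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// logical vector: row i TRUE iff no other row dominates it
// (maximize-all; duplicated rows all retained)
// [[Rcpp::export]]
LogicalVector pareto_filter_cpp(NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol();
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      bool geq = true, gt = false;
      for (int k = 0; k < d; ++k) {
        if (X(j, k) < X(i, k)) { geq = false; break; }
        if (X(j, k) > X(i, k)) gt = true;
      }
      if (geq && gt) { keep[i] = false; break; }
    }
  }
  return keep;
}

static double hv2(std::vector<std::pair<double, double> > &pts,
                  double rx, double ry) {
  // exact 2-D hypervolume (maximization); pts need not be filtered
  if (pts.empty()) return 0.0;
  std::sort(pts.begin(), pts.end(),
            [](const std::pair<double, double> &a,
               const std::pair<double, double> &b) {
              return a.first > b.first;
            });
  double hv = 0.0, ylast = ry;
  for (size_t i = 0; i < pts.size(); ++i) {
    if (pts[i].second > ylast) {
      hv += (pts[i].first - rx) * (pts[i].second - ylast);
      ylast = pts[i].second;
    }
  }
  return hv;
}

// exact hypervolume for d in {1,2,3}; every point must dominate ref
// [[Rcpp::export]]
double hv_exact_cpp(NumericMatrix P, NumericVector ref) {
  const int n = P.nrow(), d = P.ncol();
  if (n == 0) return 0.0;
  if (d == 1) {
    double m = P(0, 0);
    for (int i = 1; i < n; ++i) m = std::max(m, P(i, 0));
    return m - ref[0];
  }
  if (d == 2) {
    std::vector<std::pair<double, double> > pts(n);
    for (int i = 0; i < n; ++i) pts[i] = {P(i, 0), P(i, 1)};
    return hv2(pts, ref[0], ref[1]);
  }
  if (d != 3) stop("hv_exact_cpp handles 1-3 objectives");
  // sweep the third coordinate downwards; between consecutive levels
  // the dominated region is the 2-D union over points with z >= level
  std::vector<double> zs(n);
  for (int i = 0; i < n; ++i) zs[i] = P(i, 2);
  std::sort(zs.begin(), zs.end(), std::greater<double>());
  zs.erase(std::unique(zs.begin(), zs.end()), zs.end());
  double hv = 0.0;
  for (size_t l = 0; l < zs.size(); ++l) {
    const double zhi = zs[l];
    const double zlo = (l + 1 < zs.size()) ? zs[l + 1] : ref[2];
    std::vector<std::pair<double, double> > slab;
    for (int i = 0; i < n; ++i)
      if (P(i, 2) >= zhi) slab.push_back({P(i, 0), P(i, 1)});
    hv += hv2(slab, ref[0], ref[1]) * (zhi - zlo);
  }
  return hv;
}
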