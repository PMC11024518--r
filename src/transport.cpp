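#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Successive-shortest-path transportation solver (Dijkstra on reduced
// costs with Johnson potentials). Exact for the small dense instances
// arising from graph-curvature measures and diagram matchings.
// [[Rcpp::export]]
List transport_ssp_cpp(NumericVector a, NumericVector b, NumericMatrix C,
                       double tol) {
  const int m = a.size(), n = b.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix f(m, n);
  std::vector<double> pis(m, 0.0), pit(n, 0.0);
  std::vector<double> ar(a.begin(), a.end()), br(b.begin(), b.end());
  double rem = 0.0;
  for (int i = 0; i < m; ++i) rem += ar[i];
  long guard = 0, maxit = 20L * (m + n) * (m + n);
  while (rem > tol) {
    if (++guard > maxit) stop("transport solver failed to converge");
    std::vector<double> ds(m, INF), dt(n, INF);
    std::vector<int> parT(n, -1), parS(m, -1);
    std::vector<char> doneS(m, 0), doneT(n, 0);
    for (int i = 0; i < m; ++i) if (ar[i] > tol) ds[i] = 0.0;
    while (true) {
      double best = INF; int bi = -1; bool isS = true;
      for (int i = 0; i < m; ++i)
        if (!doneS[i] && ds[i] < best) { best = ds[i]; bi = i; isS = true; }
      for (int j = 0; j < n; ++j)
        if (!doneT[j] && dt[j] < best) { best = dt[j]; bi = j; isS = false; }
      if (bi < 0) break;
      if (isS) {
        int i = bi; doneS[i] = 1;
        for (int j = 0; j < n; ++j) {
          if (doneT[j]) continue;
          double rc = C(i, j) - pis[i] - pit[j];
          if (rc < 0) rc = 0;
          double nd = ds[i] + rc;
          if (nd < dt[j]) { dt[j] = nd; parT[j] = i; }
        }
      } else {
        int j = bi; doneT[j] = 1;
        for (int i = 0; i < m; ++i)
          if (!doneS[i] && f(i, j) > tol && dt[j] < ds[i]) {
            ds[i] = dt[j]; parS[i] = j;
          }
      }
    }
    int t = -1; double bestd = INF;
    for (int j = 0; j < n; ++j)
      if (br[j] > tol && dt[j] < bestd) { bestd = dt[j]; t = j; }
    if (t < 0 || !std::isfinite(bestd))
      stop("transport infeasible: supports not mutually reachable");
    double Dstar = dt[t];
    std::vector<std::pair<int, int> > fw, bw;
    int j = t, root = -1;
    while (true) {
      int i = parT[j];
      fw.push_back(std::make_pair(i, j));
      int jp = parS[i];
      if (jp < 0) { root = i; break; }
      bw.push_back(std::make_pair(i, jp));
      j = jp;
    }
    double delta = std::min(ar[root], br[t]);
    for (size_t e = 0; e < bw.size(); ++e)
      delta = std::min(delta, f(bw[e].first, bw[e].second));
    for (size_t e = 0; e < fw.size(); ++e)
      f(fw[e].first, fw[e].second) += delta;
    for (size_t e = 0; e < bw.size(); ++e)
      f(bw[e].first, bw[e].second) -= delta;
    ar[root] -= delta; br[t] -= delta; rem -= delta;
    for (int i = 0; i < m; ++i)
      pis[i] -= std::min(ds[i], Dstar);
    for (int j2 = 0; j2 < n; ++j2)
      pit[j2] += std::min(dt[j2], Dstar);
  }
  double cost = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j2 = 0; j2 < n; ++j2) cost += f(i, j2) * C(i, j2);
  return List::create(_["cost"] = cost, _["plan"] = f);
}
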