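#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static IntegerMatrix reduce_core(std::vector< std::vector<int> >& cols) {
  int m = cols.size();
  std::vector<int> pivot_owner(m, -1);
  std::vector<int> death_of(m, -1);
  std::vector<int> tmp;
  for (int j = 0; j < m; ++j) {
    std::vector<int>& c = cols[j];
    while (!c.empty()) {
      int low = c.back();
      int k = pivot_owner[low];
      if (k < 0) break;
      const std::vector<int>& d = cols[k];
      tmp.clear();
      size_t a = 0, b = 0;
      while (a < c.size() && b < d.size()) {
        if (c[a] < d[b]) tmp.push_back(c[a++]);
        else if (d[b] < c[a]) tmp.push_back(d[b++]);
        else { ++a; ++b; }
      }
      while (a < c.size()) tmp.push_back(c[a++]);
      while (b < d.size()) tmp.push_back(d[b++]);
      c.swap(tmp);
    }
    if (!c.empty()) {
      int low = c.back();
      pivot_owner[low] = j;
      death_of[low] = j;
    }
  }
  int npairs = 0;
  for (int i = 0; i < m; ++i) if (death_of[i] >= 0) ++npairs;
  IntegerMatrix out(2, npairs);
  int p = 0;
  for (int i = 0; i < m; ++i) {
    if (death_of[i] >= 0) {
      out(0, p) = i;
      out(1, p) = death_of[i];
      ++p;
    }
  }
  return out;
}

// Z/2 boundary-matrix reduction (standard persistence pairing).
// `boundaries` holds, per column, the 0-based positions of the column's
// facets in filtration order (strictly increasing). Columns are processed
// left to right; a pivot table maps each low entry to the column that owns
// it so collisions resolve in a single lookup instead of a scan.
// Returns a 2 x npairs matrix of (birth, death) column positions, 0-based.
// [[Rcpp::export]]
IntegerMatrix reduce_boundary_cpp(List boundaries) {
  int m = boundaries.size();
  std::vector< std::vector<int> > cols(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector b = boundaries[j];
    cols[j].assign(b.begin(), b.end());
  }
  return reduce_core(cols);
}

// Flat-input variant avoiding per-column R vectors: column j's facet
// positions are entries[colptr[j] .. colptr[j+1]-1] (0-based, sorted).
// [[Rcpp::export]]
IntegerMatrix reduce_boundary_flat_cpp(IntegerVector entries,
                                       IntegerVector colptr) {
  int m = colptr.size() - 1;
  std::vector< std::vector<int> > cols(m);
  for (int j = 0; j < m; ++j) {
    int s = colptr[j], e = colptr[j + 1];
    cols[j].assign(entries.begin() + s, entries.begin() + e);
  }
  return reduce_core(cols);
}
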