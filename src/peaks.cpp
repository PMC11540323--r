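#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Topological persistence on a 2D grid: sweep values high to low, track
// connected-component births (peaks) and deaths (merges) with union-find,
// 8-neighbourhood. Cells with value <= 0 are background.

// [[Rcpp::export(name = ".cpp_persistence_peaks")]]
DataFrame cpp_persistence_peaks(const NumericMatrix& v) {
  const int nr = v.nrow(), nc = v.ncol();
  const int n = nr * nc;
  std::vector<int> cells;
  cells.reserve(n);
  for (int i = 0; i < n; ++i) if (v[i] > 0) cells.push_back(i);
  std::stable_sort(cells.begin(), cells.end(),
                   [&](int a, int b) { return v[a] > v[b]; });
  std::vector<int> parent(n, -1);   // -1 = unvisited; roots are birth cells
  std::vector<double> birth(n, 0.0);
  std::vector<double> pers(n, -1.0); // persistence recorded at death, by birth cell
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  for (int cell : cells) {
    double lev = v[cell];
    int r = cell % nr, c = cell / nr;
    int roots[8];
    int nroots = 0;
    for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int nb = cc * nr + rr;
      if (parent[nb] < 0) continue;
      int rt = find(nb);
      bool dup = false;
      for (int j = 0; j < nroots; ++j) if (roots[j] == rt) { dup = true; break; }
      if (!dup) roots[nroots++] = rt;
    }
    if (nroots == 0) {
      parent[cell] = cell;
      birth[cell] = lev;
    } else {
      // oldest (highest-birth) neighbouring component absorbs the rest
      int keep = roots[0];
      for (int j = 1; j < nroots; ++j)
        if (birth[roots[j]] > birth[keep]) keep = roots[j];
      parent[cell] = keep;
      for (int j = 0; j < nroots; ++j) {
        int rt = roots[j];
        if (rt == keep) continue;
        pers[rt] = birth[rt] - lev;
        parent[rt] = keep;
      }
    }
  }
  // birth[] is set only for cells that created a component (birth cells);
  // a component that never died persists down to the zero level
  std::vector<int> bcell;
  std::vector<double> bval, p;
  for (int i = 0; i < n; ++i) {
    if (parent[i] < 0 || birth[i] <= 0.0) continue;
    bcell.push_back(i);
    bval.push_back(birth[i]);
    p.push_back(pers[i] >= 0 ? pers[i] : birth[i]);
  }
  IntegerVector row(bcell.size()), col(bcell.size());
  NumericVector bb(bcell.size()), pp(bcell.size());
  for (size_t i = 0; i < bcell.size(); ++i) {
    row[i] = bcell[i] % nr + 1;
    col[i] = bcell[i] / nr + 1;
    bb[i] = bval[i];
    pp[i] = p[i];
  }
  return DataFrame::create(_["bx"] = row, _["by"] = col,
                           _["birth"] = bb, _["persistence"] = pp);
}
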