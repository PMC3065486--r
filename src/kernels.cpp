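#include <Rcpp.h>
#include <sstream>
#include <iomanip>
#include <vector>
#include <string>
using namespace Rcpp;

// Pairwise Kimura 2-parameter distances under pairwise deletion.
//
// seqs: n x L integer matrix, rows are specimens; codes 0=A,1=C,2=G,3=T,
// -1 = ambiguous/gap (excluded per pair). Transitions are A<->G and C<->T,
// i.e. codes of equal parity.
//
// Sentinels in d: NA_REAL  -> zero comparable sites for that pair
//                 -1.0     -> saturated pair (log argument <= 0)
// The R wrapper turns sentinels into errors naming the pair.
// [[Rcpp::export(name = ".k2p_engine")]]
List k2p_engine(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix d(n, n);
  IntegerMatrix sites(n, n);
  // pack into contiguous buffer for cache-friendly row access
  std::vector<signed char> s((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j)
      s[(size_t)i * L + j] = (signed char)seqs(i, j);
  for (int i = 0; i < n; ++i) {
    int un = 0;
    const signed char *ri = &s[(size_t)i * L];
    for (int k = 0; k < L; ++k) if (ri[k] >= 0) ++un;
    sites(i, i) = un;
    d(i, i) = 0.0;
  }
  for (int i = 0; i < n; ++i) {
    const signed char *ri = &s[(size_t)i * L];
    for (int j = i + 1; j < n; ++j) {
      const signed char *rj = &s[(size_t)j * L];
      int comp = 0, ts = 0, tv = 0;
      for (int k = 0; k < L; ++k) {
        const signed char a = ri[k], b = rj[k];
        if (a < 0 || b < 0) continue;
        ++comp;
        if (a != b) {
          if ((a & 1) == (b & 1)) ++ts; else ++tv;
        }
      }
      sites(i, j) = sites(j, i) = comp;
      double dij;
      if (comp == 0) {
        dij = NA_REAL;
      } else {
        const double P = (double)ts / comp, Q = (double)tv / comp;
        const double w1 = 1.0 - 2.0 * P - Q, w2 = 1.0 - 2.0 * Q;
        if (w1 <= 0.0 || w2 <= 0.0)
          dij = -1.0;                       // saturation sentinel
        else
          dij = -0.5 * std::log(w1) - 0.25 * std::log(w2) + 0.0; // avoid -0
      }
      d(i, j) = d(j, i) = dij;
    }
  }
  return List::create(_["d"] = d, _["sites"] = sites);
}

static std::string fmt_bl(double v) {
  std::ostringstream os;
  os << std::setprecision(17) << v;
  return os.str();
}

// Saitou & Nei neighbour joining with lexicographic tie-breaking on the
// Q criterion and negative branch lengths clamped to zero (the deficit is
// transferred to the sister branch so the joined pair's path length is
// preserved). Emits Newick with placeholder tips t1..tn; the R wrapper
// restores real labels via ape::read.tree.
// [[Rcpp::export(name = ".nj_engine")]]
List nj_engine(NumericMatrix dist) {
  const int n = dist.nrow();
  std::vector<double> negs;
  if (n == 2) {
    const double h = dist(0, 1) / 2.0;
    std::string nwk = "(t1:" + fmt_bl(h) + ",t2:" + fmt_bl(h) + ");";
    return List::create(_["newick"] = nwk,
                        _["negative_branches"] = NumericVector(negs.begin(), negs.end()));
  }
  std::vector<std::vector<double> > D(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[i][j] = dist(i, j);
  std::vector<std::string> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = "t" + std::to_string(i + 1);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  int r = n;
  while (r > 3) {
    std::vector<double> R(r, 0.0);
    for (int a = 0; a < r; ++a)
      for (int b = 0; b < r; ++b)
        if (a != b) R[a] += D[act[a]][act[b]];
    double best = R_PosInf;
    int ba = -1, bb = -1;
    for (int a = 0; a < r; ++a) {
      for (int b = a + 1; b < r; ++b) {
        const double q = (r - 2) * D[act[a]][act[b]] - R[a] - R[b];
        if (q < best) { best = q; ba = a; bb = b; }
      }
    }
    const int i = act[ba], j = act[bb];
    const double dij = D[i][j];
    double li = 0.5 * dij + (R[ba] - R[bb]) / (2.0 * (r - 2));
    double lj = dij - li;
    if (li < 0.0) { negs.push_back(li); lj += li; li = 0.0; }
    if (lj < 0.0) { negs.push_back(lj); li += lj; lj = 0.0; }
    if (li < 0.0) { li = 0.0; }
    for (int a = 0; a < r; ++a) {
      const int k = act[a];
      if (k == i || k == j) continue;
      const double nd = 0.5 * (D[i][k] + D[j][k] - dij);
      D[i][k] = D[k][i] = nd;
    }
    lab[i] = "(" + lab[i] + ":" + fmt_bl(li) + "," + lab[j] + ":" + fmt_bl(lj) + ")";
    act.erase(act.begin() + bb);
    --r;
  }
  const int x = act[0], y = act[1], z = act[2];
  double a3 = 0.5 * (D[x][y] + D[x][z] - D[y][z]);
  double b3 = 0.5 * (D[x][y] + D[y][z] - D[x][z]);
  double c3 = 0.5 * (D[x][z] + D[y][z] - D[x][y]);
  if (a3 < 0.0) { negs.push_back(a3); a3 = 0.0; }
  if (b3 < 0.0) { negs.push_back(b3); b3 = 0.0; }
  if (c3 < 0.0) { negs.push_back(c3); c3 = 0.0; }
  std::string nwk = "(" + lab[x] + ":" + fmt_bl(a3) + "," + lab[y] + ":" +
                    fmt_bl(b3) + "," + lab[z] + ":" + fmt_bl(c3) + ");";
  return List::create(_["newick"] = nwk,
                      _["negative_branches"] = NumericVector(negs.begin(), negs.end()));
}
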