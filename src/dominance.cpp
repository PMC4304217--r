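#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Fenwick tree over d-ranks; supports point insert and prefix-sum query.
struct Fenwick {
  std::vector<int> t;
  explicit Fenwick(int n) : t(n + 1, 0) {}
  void add(int i) {
    for (++i; i < (int)t.size(); i += i & -i) t[i]++;
  }
  // sum over ranks [0, i)
  long long prefix(int i) const {
    long long s = 0;
    for (; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

// For each query q, counts the null points with l[j] < L[q] AND d[j] < D[q]
// (both strict). Offline sweep: points and queries sorted by the first
// coordinate, second coordinate counted through a Fenwick tree over ranks.
// [[Rcpp::export]]
NumericVector count_dominated(NumericVector l, NumericVector d,
                              NumericVector L, NumericVector D) {
  const int np = l.size(), nq = L.size();
  if (d.size() != np || D.size() != nq)
    stop("coordinate vectors must have matching lengths");

  std::vector<double> dsort(d.begin(), d.end());
  std::sort(dsort.begin(), dsort.end());
  dsort.erase(std::unique(dsort.begin(), dsort.end()), dsort.end());

  std::vector<int> pord(np), qord(nq);
  for (int i = 0; i < np; ++i) pord[i] = i;
  for (int i = 0; i < nq; ++i) qord[i] = i;
  std::sort(pord.begin(), pord.end(),
            [&](int a, int b) { return l[a] < l[b]; });
  std::sort(qord.begin(), qord.end(),
            [&](int a, int b) { return L[a] < L[b]; });

  Fenwick fw((int)dsort.size());
  NumericVector out(nq);
  int ip = 0;
  for (int iq = 0; iq < nq; ++iq) {
    const int q = qord[iq];
    while (ip < np && l[pord[ip]] < L[q]) {
      const int j = pord[ip];
      const int rk = (int)(std::lower_bound(dsort.begin(), dsort.end(), d[j]) -
                           dsort.begin());
      fw.add(rk);
      ++ip;
    }
    // rank of D[q] = number of distinct d-values strictly below D[q]
    const int rq = (int)(std::lower_bound(dsort.begin(), dsort.end(), D[q]) -
                         dsort.begin());
    out[q] = (double)fw.prefix(rq);
  }
  return out;
}
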