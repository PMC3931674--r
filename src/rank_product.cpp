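#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Per-column fold-change ranks (average ranks on ties) accumulated as
// mean log ranks for both regulation directions. Column j holds the
// fold changes of one pairwise case-vs-control comparison; ascending
// rank r is the "down" rank, G + 1 - r the "up" rank. Returns the mean
// of log ranks per gene, i.e. log of the geometric-mean rank.
// [[Rcpp::export(name = ".rpLogRankMeans")]]
List rpLogRankMeans(NumericMatrix fc) {
  const int G = fc.nrow(), K = fc.ncol();
  std::vector<double> sumUp(G, 0.0), sumDown(G, 0.0);
  std::vector<int> idx(G);
  for (int j = 0; j < K; ++j) {
    NumericMatrix::Column col = fc(_, j);
    std::iota(idx.begin(), idx.end(), 0);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < G) {
      int h = i;
      while (h + 1 < G && col[idx[h + 1]] == col[idx[i]]) ++h;
      const double avg = (i + h) / 2.0 + 1.0;  // 1-based average rank
      const double logDown = std::log(avg);
      const double logUp = std::log(G + 1 - avg);
      for (int t = i; t <= h; ++t) {
        sumDown[idx[t]] += logDown;
        sumUp[idx[t]] += logUp;
      }
      i = h + 1;
    }
  }
  NumericVector up(G), down(G);
  for (int g = 0; g < G; ++g) {
    up[g] = sumUp[g] / K;
    down[g] = sumDown[g] / K;
  }
  return List::create(_["up"] = up, _["down"] = down);
}
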