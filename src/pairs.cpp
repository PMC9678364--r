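// Spatial-hash candidate pair search: all site pairs on distinct
// filaments with separation inside [win_lo, win_hi].  Cell size equals
// the window maximum, so only 27 neighbor cells need scanning.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".find_pairs_cpp")]]
List find_pairs_cpp(NumericMatrix pos, IntegerVector fil,
                    double win_lo, double win_hi) {
  const int n = pos.nrow();
  std::vector<int> out_i, out_j;
  std::vector<double> out_d;
  if (n >= 2) {
    const double cell = win_hi;
    const double lo2 = win_lo * win_lo, hi2 = win_hi * win_hi;
    auto key = [&](double x, double y, double z) -> long long {
      long long ix = (long long)std::floor(x / cell) + 1024;
      long long iy = (long long)std::floor(y / cell) + 1024;
      long long iz = (long long)std::floor(z / cell) + 1024;
      return (ix * 4096 + iy) * 4096 + iz;
    };
    std::unordered_map<long long, std::vector<int>> cells;
    std::vector<long long> ks(n);
    for (int i = 0; i < n; ++i) {
      ks[i] = key(pos(i, 0), pos(i, 1), pos(i, 2));
      cells[ks[i]].push_back(i);
    }
    const long long offs[27][3] = {
      {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
      {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
      {0,0,-1},{0,0,0},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
      {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},
      {1,1,-1},{1,1,0},{1,1,1}};
    for (auto &kv : cells) {
      long long k0 = kv.first;
      for (int o = 0; o < 27; ++o) {
        long long nb = k0 + (offs[o][0] * 4096 + offs[o][1]) * 4096 +
                       offs[o][2];
        if (nb < k0) continue;            // each cell pair once
        auto it = cells.find(nb);
        if (it == cells.end()) continue;
        const std::vector<int> &A = kv.second;
        const std::vector<int> &B = it->second;
        const bool same = (nb == k0);
        for (size_t a = 0; a < A.size(); ++a) {
          size_t bstart = same ? a + 1 : 0;
          for (size_t b = bstart; b < B.size(); ++b) {
            int i = A[a], j = B[b];
            if (fil[i] == fil[j]) continue;
            double dx = pos(i, 0) - pos(j, 0);
            double dy = pos(i, 1) - pos(j, 1);
            double dz = pos(i, 2) - pos(j, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < lo2 || d2 > hi2) continue;
            out_i.push_back(i + 1);
            out_j.push_back(j + 1);
            out_d.push_back(std::sqrt(d2));
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["d"] = wrap(out_d));
}
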