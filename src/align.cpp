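// Banded dynamic-programming alignment of a molecule's label positions to a
// map's label positions. Matched label pairs are scored by inter-label
// interval agreement (relative absolute difference); skipped map labels pay
// a miss penalty, skipped molecule labels an extra-label penalty. The
// molecule is aligned near-globally (unmatched molecule labels at either
// end pay the extra penalty), the map end-free (the molecule is a window).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List align_dp_cpp(NumericVector mol, NumericVector ref, double match_bonus,
                  double interval_weight, double miss_penalty,
                  double extra_penalty, int band) {
  const int M = mol.size(), N = ref.size();
  if (M == 0 || N == 0) {
    return List::create(_["score"] = R_NegInf,
                        _["mol_idx"] = IntegerVector(0),
                        _["ref_idx"] = IntegerVector(0));
  }
  const double *pm = &mol[0];
  const double *pr = &ref[0];
  std::vector<double> S((size_t)M * N);
  std::vector<int> P((size_t)M * N, -1); // packed predecessor: pi * N + pj
  double best = R_NegInf;
  int bcell = -1;
  for (int i = 0; i < M; ++i) {
    const double start_s = match_bonus - extra_penalty * i;
    double *Si = &S[(size_t)i * N];
    int *Pi = &P[(size_t)i * N];
    for (int j = 0; j < N; ++j) {
      double s = start_s; // fresh start at (i, j)
      int p = -1;
      const int dimax = std::min(band, i);
      const int djmax = std::min(band, j);
      for (int di = 1; di <= dimax; ++di) {
        const double dm = pm[i] - pm[i - di];
        const double *Sp = &S[(size_t)(i - di) * N];
        const double skip = match_bonus - extra_penalty * (di - 1);
        for (int dj = 1; dj <= djmax; ++dj) {
          const double dr = pr[j] - pr[j - dj];
          const double rel = std::abs(dm - dr) / (dr > 500.0 ? dr : 500.0);
          const double cand = Sp[j - dj] + skip - interval_weight * rel -
                              miss_penalty * (dj - 1);
          if (cand > s) {
            s = cand;
            p = (i - di) * N + (j - dj);
          }
        }
      }
      Si[j] = s;
      Pi[j] = p;
      const double fin = s - extra_penalty * (M - 1 - i);
      // ties broken toward the lower map offset (first maximum kept)
      if (fin > best + 1e-12) {
        best = fin;
        bcell = i * N + j;
      }
    }
  }
  std::vector<int> mi, rj;
  int cell = bcell;
  while (cell >= 0) {
    mi.push_back(cell / N + 1);
    rj.push_back(cell % N + 1);
    cell = P[cell];
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(rj.begin(), rj.end());
  return List::create(_["score"] = best, _["mol_idx"] = wrap(mi),
                      _["ref_idx"] = wrap(rj));
}
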