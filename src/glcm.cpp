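#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window GLCM Haralick metrics averaged over all window centers whose
// full window lies inside one plot's mask footprint. Gray levels in q must be
// 0..nlevels-1. Offset (dx, dy) = (+dx columns, +dy rows), non-symmetric by
// default. Returns the 8 metric means followed by the window count.
//
// Moment-based metrics (mean, variance, contrast, dissimilarity, homogeneity,
// correlation) are accumulated directly over the ordered pairs; only entropy
// and the angular second moment need the co-occurrence cell counts, which are
// kept in a scratch table cleared via a touched-cell list.
// [[Rcpp::export]]
NumericVector glcm_plot_metrics(IntegerMatrix q, IntegerMatrix mask,
                                int plot_id, int window, int dx, int dy,
                                int nlevels, bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  const int half = window / 2;

  // prefix sums of mask membership for O(1) full-window tests
  std::vector<int> S((nr + 1) * (size_t)(nc + 1), 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      S[(size_t)(r + 1) * (nc + 1) + (c + 1)] =
          S[(size_t)r * (nc + 1) + (c + 1)] +
          S[(size_t)(r + 1) * (nc + 1) + c] - S[(size_t)r * (nc + 1) + c] +
          (mask(r, c) == plot_id ? 1 : 0);
  auto boxsum = [&](int r0, int c0, int r1, int c1) -> int {
    return S[(size_t)(r1 + 1) * (nc + 1) + (c1 + 1)] -
           S[(size_t)r0 * (nc + 1) + (c1 + 1)] -
           S[(size_t)(r1 + 1) * (nc + 1) + c0] + S[(size_t)r0 * (nc + 1) + c0];
  };

  const int pr = window - std::abs(dy);  // pair rows per window
  const int pc = window - std::abs(dx);
  if (pr < 1 || pc < 1) stop("offset reach exceeds the window");
  const int npairs = pr * pc * (symmetric ? 2 : 1);

  // lookup tables: 1/(1+d^2), |d|, c*log(c)
  std::vector<double> inv1d2(nlevels), absd(nlevels);
  for (int d = 0; d < nlevels; ++d) {
    inv1d2[d] = 1.0 / (1.0 + (double)d * d);
    absd[d] = d;
  }
  std::vector<double> clogc(npairs + 1, 0.0);
  for (int c = 1; c <= npairs; ++c) clogc[c] = c * std::log((double)c);
  const double tot = npairs, log_tot = std::log(tot);

  std::vector<int> cnt((size_t)nlevels * nlevels, 0);
  std::vector<int> touched;
  touched.reserve(npairs);
  const int* qp = q.begin();  // column-major, nr rows

  double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  long long nwin = 0;

  for (int cc = half; cc < nc - half; ++cc) {
    for (int cr = half; cr < nr - half; ++cr) {
      const int r0 = cr - half, c0 = cc - half;
      if (boxsum(r0, c0, r0 + window - 1, c0 + window - 1) != window * window)
        continue;
      touched.clear();
      long long sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      double hom = 0, con = 0, dis = 0;
      for (int j = 0; j < pc; ++j) {
        const int* colA = qp + (size_t)(c0 + j) * nr + r0;
        const int* colB = qp + (size_t)(c0 + j + dx) * nr + r0 + dy;
        for (int i = 0; i < pr; ++i) {
          const int a = colA[i], b = colB[i];
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
          const int d = a < b ? b - a : a - b;
          hom += inv1d2[d];
          con += (double)d * d;
          dis += absd[d];
          int k = a * nlevels + b;
          if (cnt[k]++ == 0) touched.push_back(k);
          if (symmetric) {
            k = b * nlevels + a;
            if (cnt[k]++ == 0) touched.push_back(k);
          }
        }
      }
      double ent = 0, asm_ = 0;
      for (int k : touched) {
        const int c = cnt[k];
        ent += clogc[c];
        asm_ += (double)c * c;
        cnt[k] = 0;
      }
      ent = log_tot - ent / tot;
      asm_ /= tot * tot;
      // hom/con/dis depend only on |i-j|, so the per-ordered-pair mean equals
      // the symmetric-matrix value as well
      const double nord = (double)pr * pc;
      hom /= nord; con /= nord; dis /= nord;
      double mu_i, mu_j, var_i, var_j, cov;
      if (symmetric) {
        // symmetric accumulation counts every pair in both orders
        mu_i = mu_j = (sa + sb) / (2.0 * nord);
        var_i = var_j = (saa + sbb) / (2.0 * nord) - mu_i * mu_i;
        cov = (double)sab / nord - mu_i * mu_j;
      } else {
        mu_i = (double)sa / nord;
        mu_j = (double)sb / nord;
        var_i = (double)saa / nord - mu_i * mu_i;
        var_j = (double)sbb / nord - mu_j * mu_j;
        cov = (double)sab / nord - mu_i * mu_j;
      }
      var_i = var_i < 0 ? 0 : var_i;
      var_j = var_j < 0 ? 0 : var_j;
      const double sig = std::sqrt(var_i * var_j);
      const double cor = (sig == 0.0) ? 1.0 : cov / sig;
      acc[0] += mu_i;
      acc[1] += var_i;
      acc[2] += hom;
      acc[3] += con;
      acc[4] += dis;
      acc[5] += ent;
      acc[6] += asm_;
      acc[7] += cor;
      ++nwin;
    }
  }

  NumericVector out(9);
  for (int m = 0; m < 8; ++m) out[m] = nwin > 0 ? acc[m] / nwin : NA_REAL;
  out[8] = (double)nwin;
  return out;
}
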